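# Shared brute-force helpers for the test suite. These deliberately use
# different primitives than the implementation (per-base boolean masks,
# iterated matrix products, explicit path enumeration).

# boolean coverage mask of an annotation over [0, L)
coverage_mask <- function(starts, ends, L) {
  mask <- logical(L)
  for (i in seq_along(starts)) mask[seq.int(starts[i] + 1, ends[i])] <- TRUE
  mask
}

# K(R, Q) via per-base masks: count reference intervals whose positions
# intersect the query's covered set
overlap_count_mask <- function(R, Q) {
  qmask <- coverage_mask(Q$starts, Q$ends, Q$L)
  sum(vapply(seq_along(R$starts), function(i)
    any(qmask[seq.int(R$starts[i] + 1, R$ends[i])]), TRUE))
}

# naive iterated matrix product
naive_power <- function(M, a) {
  out <- diag(2)
  for (i in seq_len(a)) out <- out %*% M
  out
}

T_of <- function(params)
  matrix(c(params$t00, params$t10, params$t01, params$t11), 2L, 2L)

Tmod_of <- function(params)
  matrix(c(params$t00, params$t10, 0, 0), 2L, 2L)

# probability of every binary path of `steps` states appended to start
# state i0, summed over paths satisfying `keep(path)` and ending in state s_end
enum_path_prob <- function(i0, steps, params, keep = function(path) TRUE,
                           s_end = NULL) {
  stopifnot(steps <= 14)
  tm <- T_of(params)
  paths <- as.matrix(expand.grid(rep(list(0:1), steps)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    path <- paths[r, ]
    if (!is.null(s_end) && path[steps] != s_end) next
    if (!keep(path)) next
    p <- tm[i0 + 1L, path[1L] + 1L]
    for (st in seq_len(steps - 1L))
      p <- p * tm[path[st] + 1L, path[st + 1L] + 1L]
    tot <- tot + p
  }
  tot
}

# random separated annotation whose first interval starts at >= 1
random_annotation <- function(L, m, max_len = 3) {
  if (m == 0L) return(annotation(numeric(0), numeric(0), L))
  repeat {
    lens_r <- sample(max_len, m, replace = TRUE)
    if (sum(lens_r) + m - 1 <= L - 1) break
  }
  repeat {
    a <- sample_gold(lens_r, L)
    if (length(a$starts) == 0L || a$starts[1L] >= 1) return(a)
  }
}

random_params <- function() {
  markov_params(t01 = stats::runif(1, 0.05, 0.9),
                t10 = stats::runif(1, 0.05, 0.9))
}

# the worked NP-hardness reduction fixture: L = 22, two reference
# intervals, query lengths {1,1,1,1,3,6}
fig_instance <- function() {
  list(R = annotation(c(6, 14), c(8, 16), L = 22),
       lens_Q = c(1, 1, 1, 1, 3, 6),
       L = 22)
}
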