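# Shared internal helpers: typed conditions and small numerics.

.mrmStop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mrm_error")))
}

mrmConfigError <- function(msg) .mrmStop(msg, "mrm_config_error")
mrmDataError   <- function(msg) .mrmStop(msg, "mrm_data_error")
mrmFitError    <- function(msg) .mrmStop(msg, "mrm_fit_error")

# row-wise summaries tolerant of all-NA rows
.rowMedians <- function(m) apply(m, 1L, function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0L) NA_real_ else median(v)
})

.colMedians <- function(m) apply(m, 2L, function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0L) NA_real_ else median(v)
})

# sum-to-zero contrast matrix: n levels -> n x (n-1)
.contrSum <- function(n) {
  C <- diag(1, nrow = n, ncol = n - 1L)
  C[n, ] <- -1
  C
}

# connectivity of the transition-run bipartite incidence graph of observed
# cells; required for identifiability of the unbalanced two-way layout
.incidenceConnected <- function(obs, nrow, ncol) {
  # obs: 2-column matrix of (row, col) indices of observed cells
  if (nrow(obs) == 0L) return(FALSE)
  parent <- seq_len(nrow + ncol)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(obs))) {
    a <- find(obs[k, 1L])
    b <- find(nrow + obs[k, 2L])
    if (a != b) parent[a] <- b
  }
  touched <- unique(c(obs[, 1L], nrow + obs[, 2L]))
  length(unique(vapply(touched, find, integer(1)))) == 1L
}
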