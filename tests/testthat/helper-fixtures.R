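# Shared fixtures and independent reference implementations used as
# oracles. Everything here is deliberately written without calling the
# package functions it is used to check.

# small hand-written cohort: two groups, three subjects each
toy_cohort_df <- function() {
  fa <- rbind(
    c(30, 20, 25, 15, 10),
    c(32, 18, 24, 16, 10),
    c(28, 22, 26, 14, 10),
    c(25, 15, 30, 20, 10),
    c(26, 14, 31, 19, 10),
    c(24, 16, 29, 21, 10)
  )
  colnames(fa) <- c("16:0", "18:0", "18:1n-9", "20:4n-6", "22:6n-3")
  cl <- rbind(
    c(25, 20, 10, 5, 40),
    c(24, 19, 10, 6, 41),
    c(26, 21, 10, 4, 39),
    c(22, 17, 14, 12, 35),
    c(21, 16, 14, 13, 36),
    c(23, 18, 14, 11, 34)
  )
  colnames(cl) <- c("PC", "PE", "PS", "SE", "CHO")
  data.frame(
    subject_id = c("N1", "N2", "N3", "A1", "A2", "A3"),
    group = rep(c("NSL", "ALS"), each = 3),
    sex = rep(c("M", "F", "M"), 2), age = 60:65, pmd = 5:10,
    fa, cl, check.names = FALSE, stringsAsFactors = FALSE
  )
}

# full-enumeration Mann-Whitney oracle: two-sided p over all ways of
# assigning the pooled values to the first sample
mw_enumeration_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2, function(ii) u_of(pooled[ii], pooled[-ii]))
  u_obs <- u_of(x, y)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(u = u_obs, p_value = min(1, p))
}

# independent raft detector: vectorized Moore-neighbourhood order via
# matrix shifts, flood fill via igraph connected components
reference_detect <- function(groups, raft_codes, theta, min_size) {
  L <- nrow(groups)
  is_raft <- matrix(groups %in% raft_codes, L, L)
  shift <- function(m, di, dj) {
    m[(seq_len(L) - 1 + di) %% L + 1, (seq_len(L) - 1 + dj) %% L + 1]
  }
  cnt <- matrix(0, L, L)
  for (di in -1:1) for (dj in -1:1) cnt <- cnt + shift(is_raft, di, dj)
  raft_sites <- (cnt / 9) >= theta
  # lattice graph over raft sites, 4-neighbour periodic
  id <- matrix(seq_len(L * L), L, L)
  edges <- rbind(
    cbind(as.vector(id), as.vector(shift(id, 1, 0))),
    cbind(as.vector(id), as.vector(shift(id, 0, 1)))
  )
  keep <- raft_sites[edges[, 1]] & raft_sites[edges[, 2]]
  g <- igraph::graph_from_edgelist(edges[keep, , drop = FALSE],
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, L * L - igraph::vcount(g)))
  comp <- igraph::components(g)
  memb <- comp$membership[seq_len(L * L)]
  memb[!as.vector(raft_sites)] <- NA
  sizes <- table(memb)
  sizes <- sizes[sizes >= min_size]
  labels <- matrix(match(memb, as.integer(names(sizes))), L, L)
  labels[is.na(labels)] <- 0
  list(labels = labels, sizes = sort(as.integer(sizes), decreasing = TRUE),
       area_fraction = sum(labels > 0) / (L * L))
}

# canonical form for comparing two raft labelings up to label permutation
canonical_labels <- function(labels) {
  relabel <- match(as.vector(t(labels)), unique(as.vector(t(labels))[
    as.vector(t(labels)) > 0]))
  relabel[is.na(relabel)] <- 0
  matrix(relabel, nrow = nrow(labels), byrow = TRUE)
}

fast_cohort_config <- function(n_nsl = 6, n_als = 4, seed = 1L) {
  default_cohort_config(n_nsl = n_nsl, n_als = n_als, seed = seed,
                        calibrate = FALSE)
}
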