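# Independent oracles used across the test suite. These deliberately avoid
# the package's own code paths wherever they check a package computation.

# All permutations of 1:n as an (n!) x n matrix (recursive construction).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  p <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, p + (p >= i))
  }))
}

# Brute-force two-sided permutation p-value: the fraction of all rank
# permutations whose |rho| is at least the observed |rho|.
brute_spearman_p <- function(y, perms = all_permutations(length(y))) {
  n <- length(y)
  ry <- rank(y)
  nn <- n * (n^2 - 1)
  rho_obs <- 1 - 6 * sum((seq_len(n) - ry)^2) / nn
  s_perm <- rowSums((perms - matrix(ry, nrow(perms), n, byrow = TRUE))^2)
  rho_perm <- 1 - 6 * s_perm / nn
  mean(abs(rho_perm) >= abs(rho_obs) - 1e-12)
}

# A permutation of 1:n whose S = sum of squared rank displacements equals
# `target` (even, within the support), by a random transposition walk that
# accepts improving moves and occasionally sideways moves.
perm_with_S <- function(n, target) {
  y <- seq_len(n)
  cur <- 0
  stall <- 0
  while (cur != target) {
    i <- sample(n, 2)
    d <- -(y[i[1]] - i[1])^2 - (y[i[2]] - i[2])^2 +
      (y[i[2]] - i[1])^2 + (y[i[1]] - i[2])^2
    new <- cur + d
    if (abs(new - target) < abs(cur - target) ||
        (stall > 50 && abs(new - target) <= abs(cur - target) + 4 &&
         stats::runif(1) < 0.3)) {
      y[i] <- y[rev(i)]
      cur <- new
      stall <- 0
    } else {
      stall <- stall + 1
    }
  }
  y
}

# Independent brute-force screening filter over correlation result tables.
brute_screen_sets <- function(tumor, normal, alpha, rho_min, normal_p_floor) {
  pick <- function(df, side) {
    out <- character(0)
    for (i in seq_len(nrow(df))) {
      if (is.na(df$rho[i]) || is.na(df$p[i])) next
      if (df$p[i] >= alpha) next
      if (side == "pos" && df$rho[i] > rho_min) out <- c(out, df$feature_id[i])
      if (side == "neg" && df$rho[i] < -rho_min) out <- c(out, df$feature_id[i])
    }
    out
  }
  cand <- character(0)
  classified <- c(pick(tumor, "pos"), pick(tumor, "neg"))
  for (f in classified) {
    j <- match(f, normal$feature_id)
    if (is.na(j) || is.na(normal$p[j])) next
    if (normal$p[j] >= normal_p_floor) cand <- c(cand, f)
  }
  list(tumor_pos = sort(pick(tumor, "pos")),
       tumor_neg = sort(pick(tumor, "neg")),
       normal_pos = sort(pick(normal, "pos")),
       normal_neg = sort(pick(normal, "neg")),
       candidates = sort(cand))
}

# Independent brute-force integration edge filter: plain double loop over
# every (candidate, annotated target) pair.
brute_edges <- function(mirna, gene, candidates, targets, shared, alpha) {
  out <- character(0)
  for (m in candidates) {
    gs <- targets$gene[targets$mirna == m]
    for (g in gs) {
      if (!g %in% rownames(gene)) next
      x <- mirna[m, shared]
      y <- gene[g, shared]
      if (length(unique(x)) == 1L || length(unique(y)) == 1L) next
      st <- spearman_test(x, y)
      if (st$rho < 0 && st$p_two_sided < alpha)
        out <- c(out, paste(m, g))
    }
  }
  sort(out)
}

# Small random correlation-result table for property tests.
random_results <- function(n_feat, tissue, prefix = "f") {
  data.frame(
    feature_id = sprintf("%s%03d", prefix, seq_len(n_feat)),
    tissue = tissue,
    n = 30L,
    rho = stats::runif(n_feat, -1, 1),
    p = stats::runif(n_feat),
    method = "edgeworth",
    ties = FALSE,
    stringsAsFactors = FALSE
  )
}

# 49-record clinical fixture mirroring a published two-age-group cohort
# composition (28 PEDS / 21 AYA; embryonal 20/9, alveolar 8/12;
# gender M 13/13, F 15/8).
clinical_fixture <- function() {
  peds <- data.frame(
    sample_id = sprintf("P%02d", 1:28),
    age_group = "PEDS",
    histology = rep(c("Embryonal", "Alveolar"), c(20, 8)),
    gender = rep(c("Male", "Female"), c(13, 15)),
    stringsAsFactors = FALSE
  )
  aya <- data.frame(
    sample_id = sprintf("A%02d", 1:21),
    age_group = "AYA",
    histology = rep(c("Embryonal", "Alveolar"), c(9, 12)),
    gender = rep(c("Male", "Female"), c(13, 8)),
    stringsAsFactors = FALSE
  )
  rbind(peds, aya)
}

# Random tidy Ct table for the ddCt property tests.
random_ct_records <- function(n_samples = 8, assays = c("A1", "A2")) {
  do.call(rbind, lapply(assays, function(a) {
    data.frame(
      sample_id = sprintf("s%02d", seq_len(n_samples)),
      assay_id = a,
      ct_target = stats::runif(n_samples, 18, 32),
      ct_reference = stats::runif(n_samples, 15, 25),
      group = rep(c("PEDS", "AYA"), length.out = n_samples),
      stringsAsFactors = FALSE
    )
  }))
}
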