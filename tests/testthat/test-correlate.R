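make_samples <- function(n_tumor, n_normal, seed = 1) {
  set.seed(seed)
  n <- n_tumor + n_normal
  days <- sample(365:(35 * 365), n)
  data.frame(
    sample_id = c(sprintf("T%02d", seq_len(n_tumor)),
                  sprintf("N%02d", seq_len(n_normal))),
    tissue = rep(c("tumor", "normal"), c(n_tumor, n_normal)),
    age_years = days / 365,
    stringsAsFactors = FALSE
  )
}

test_that("a feature equal to age itself correlates perfectly", {
  s <- make_samples(10, 4)
  tum <- s$sample_id[s$tissue == "tumor"]
  m <- matrix(rnorm(2 * nrow(s)), 2, nrow(s),
              dimnames = list(c("age_like", "noise"), s$sample_id))
  m["age_like", tum] <- s$age_years[match(tum, s$sample_id)]
  res <- correlate_matrix(m, s, "tumor")
  expect_equal(res$rho[res$feature_id == "age_like"], 1)
  expect_lt(res$p[res$feature_id == "age_like"], 0.001)
  expect_identical(res$method[res$feature_id == "age_like"], "exact")
})

test_that("constant features are reported undefined and columns align by id", {
  s <- make_samples(12, 3)
  m <- matrix(rnorm(3 * nrow(s)), 3, nrow(s),
              dimnames = list(c("f1", "flat", "f3"), s$sample_id))
  m["flat", ] <- 5
  res <- correlate_matrix(m, s, "tumor")
  expect_true(is.na(res$rho[res$feature_id == "flat"]))
  expect_identical(res$method[res$feature_id == "flat"], "undefined")
  # shuffled column order gives identical results: alignment is by id
  res2 <- correlate_matrix(m[, rev(colnames(m))], s, "tumor")
  expect_equal(res2$rho, res$rho)
  expect_equal(res2$p, res$p)
})

test_that("correlate_matrix demands sample overlap and enough samples", {
  s <- make_samples(4, 2)
  m <- matrix(rnorm(8), 2, 4,
              dimnames = list(c("f1", "f2"), paste0("X", 1:4)))
  expect_error(correlate_matrix(m, s, "tumor"),
               class = "agemirnet_data_error")
  expect_error(
    correlate_matrix(m[, 1:2, drop = FALSE],
                     data.frame(sample_id = paste0("X", 1:2),
                                tissue = "tumor", age_years = c(1, 2)),
                     "tumor"),
    class = "agemirnet_data_error")
})

test_that("screening classifies by the strict printed thresholds", {
  mk <- function(rho, p) data.frame(feature_id = "f1", tissue = "tumor",
                                    n = 49L, rho = rho, p = p,
                                    method = "edgeworth", ties = FALSE,
                                    stringsAsFactors = FALSE)
  nrm <- function(rho, p) { d <- mk(rho, p); d$tissue <- "normal"; d }

  # both clauses met: candidate
  out <- screen(mk(0.5, 0.01), nrm(0.05, 0.9))
  expect_identical(out$tumor$class, "positive")
  expect_identical(out$tumor_specific_candidates, "f1")

  # significant in both tissues: not tumor-specific
  out <- screen(mk(0.5, 0.01), nrm(0.4, 0.02))
  expect_identical(out$tumor$class, "positive")
  expect_identical(out$normal$class, "positive")
  expect_length(out$tumor_specific_candidates, 0)

  # |rho| below the threshold: unclassified even when significant
  out <- screen(mk(0.25, 0.01), nrm(0, 0.9))
  expect_identical(out$tumor$class, "unclassified")
  expect_length(out$tumor_specific_candidates, 0)

  # boundary is strict: rho == rho_min does not classify
  out <- screen(mk(0.3, 0.01), nrm(0, 0.9))
  expect_identical(out$tumor$class, "unclassified")

  # normal p exactly at the floor is inclusive
  out <- screen(mk(0.5, 0.01), nrm(0.1, 0.05))
  expect_identical(out$tumor_specific_candidates, "f1")
})

test_that("features missing from the normal screen are ineligible", {
  tum <- data.frame(feature_id = c("f1", "f2"), tissue = "tumor", n = 49L,
                    rho = c(0.6, 0.6), p = c(0.001, 0.001),
                    method = "edgeworth", ties = FALSE,
                    stringsAsFactors = FALSE)
  nor <- data.frame(feature_id = "f1", tissue = "normal", n = 15L,
                    rho = 0.0, p = 0.9, method = "edgeworth", ties = FALSE,
                    stringsAsFactors = FALSE)
  out <- screen(tum, nor)
  expect_identical(out$tumor_specific_candidates, "f1")
  expect_identical(out$ineligible$missing_in_normal, "f2")
  expect_error(screen(tum[0, ], nor), class = "agemirnet_data_error")
})

test_that("screening sets equal the independent brute-force filter", {
  set.seed(11)
  for (i in 1:10) {
    tum <- random_results(40, "tumor")
    nor <- random_results(40, "normal")
    cfg <- screening_config(alpha = runif(1, 0.01, 0.2),
                            rho_min = runif(1, 0, 0.6),
                            normal_p_floor = runif(1, 0, 0.6))
    out <- screen(tum, nor, cfg)
    ref <- brute_screen_sets(tum, nor, cfg$alpha, cfg$rho_min,
                             cfg$normal_p_floor)
    expect_identical(sort(out$tumor$feature_id[out$tumor$class == "positive"]),
                     ref$tumor_pos)
    expect_identical(sort(out$tumor$feature_id[out$tumor$class == "negative"]),
                     ref$tumor_neg)
    expect_identical(sort(out$tumor_specific_candidates), ref$candidates)
  }
})

test_that("screening outputs are written with matching counts", {
  set.seed(12)
  out <- screen(random_results(30, "tumor"), random_results(30, "normal"))
  d <- withr::local_tempdir()
  paths <- write_screening(out, d, "mirna")
  counts <- jsonlite::read_json(paths[["summary"]])
  expect_equal(counts$tumor_positive,
               sum(out$tumor$class == "positive"))
  expect_equal(length(readLines(paths[["candidates"]])),
               length(out$tumor_specific_candidates))
})
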