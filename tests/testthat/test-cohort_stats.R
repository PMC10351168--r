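# Cohort statistics: rates, recurrence, self-dissimilarity, odds ratios,
# the logistic depletion model, and burden metrics.

test_that("neoantigenic rate handles the zero-mutation degenerate case", {
  expect_equal(neoantigenic_rate(12, 2), 6.0)
  expect_equal(neoantigenic_rate(0, 5), 0.0)
  expect_true(is.na(neoantigenic_rate(3, 0)))
  expect_error(neoantigenic_rate(-1, 5), "non-negative")
})

test_that("shared occurrence counts distinct patients with the >2 rule", {
  rec <- data.frame(
    sequence = c("AAAAAAAA", "AAAAAAAA", "AAAAAAAA", "CCCCCCCC", "CCCCCCCC"),
    patient = c("p1", "p2", "p3", "p1", "p1"))
  out <- shared_occurrence(rec)
  expect_equal(out$n_patients[out$sequence == "AAAAAAAA"], 3L)
  expect_true(out$recurrent[out$sequence == "AAAAAAAA"])
  expect_equal(out$n_patients[out$sequence == "CCCCCCCC"], 1L)
  expect_false(out$recurrent[out$sequence == "CCCCCCCC"])
  expect_equal(out$sequence[1], "AAAAAAAA")        # sorted by count
  # empty input and duplication invariance
  expect_equal(nrow(shared_occurrence(rec[0, ])), 0L)
  expect_equal(shared_occurrence(rbind(rec, rec)), out)
})

test_that("k-mer x allele interaction counts follow the window algebra", {
  never <- mock_backend(mode = "never")
  always <- mock_backend(mode = "always")
  km0 <- kmer_allele_interactions(strrep("A", 8), paste0("al", 1:3), never)
  expect_equal(nrow(km0), 1L)
  expect_equal(attr(km0, "total_interactions"), 0L)
  # 11-residue segment: 4+3+2+1 = 10 k-mers per allele
  seg <- "ACDEFGHIKLM"
  km <- kmer_allele_interactions(seg, c("al1", "al2"), always)
  expect_equal(nrow(km), 10L)
  expect_equal(attr(km, "total_interactions"), 20L)
  expect_equal(km$log10_interactions, log10(km$n_interactions + 1))
})

test_that("self-similarity scores equal the BLOSUM62 diagonal on identity", {
  res <- self_dissimilarity("CCCCCCCC", "CCCCCCCC")
  expect_equal(res$score, 72)                       # 8 x BLOSUM62 C:C = 9
  expect_equal(res$class, "HIGH")
  # strict boundary: an exact diagonal sum of 35 is still LOW
  p35 <- paste0(strrep("A", 7), "P")                # 7*4 + 7 = 35
  expect_equal(self_dissimilarity(p35, p35)$score, 35)
  expect_equal(self_dissimilarity(p35, p35)$class, "LOW")
  p39 <- paste0(strrep("A", 7), "W")                # 7*4 + 11 = 39
  expect_equal(self_dissimilarity(p39, p39)$class, "HIGH")
  # empty peptidome
  empty <- self_dissimilarity("CCCCCCCC", character(0))
  expect_true(is.na(empty$score))
  expect_equal(empty$class, "LOW")
  # property: identity score is the diagonal sum, always >= 4 * length
  data("BLOSUM62", package = "Biostrings", envir = environment())
  set.seed(8)
  aas <- rownames(BLOSUM62)[1:20]
  for (i in 1:10) {
    p <- paste(sample(aas, sample(8:11, 1), TRUE), collapse = "")
    diag_sum <- sum(vapply(strsplit(p, "")[[1]],
                           function(a) BLOSUM62[a, a], numeric(1)))
    sc <- self_dissimilarity(p, p)$score
    expect_equal(sc, diag_sum)
    expect_gte(sc, 4 * nchar(p))
  }
})

test_that("full-protein and k-mer peptidome modes agree", {
  fx <- toy_fixture()
  proteome <- fx$ref$proteome
  kmers <- peptidome_kmers(proteome)
  set.seed(21)
  queries <- c(
    substr(proteome[[1]], 5, 13),                       # a self 9-mer
    "WWWWYYYYK",                                        # unrelated
    paste(sample(c("A","R","N","D","C","Q","E","G"), 10, TRUE), collapse = ""))
  for (q in queries) {
    a <- self_dissimilarity(q, proteome, mode = "protein")
    b <- self_dissimilarity(q, kmers, mode = "kmer")
    expect_equal(a$score, b$score, info = q)
    expect_equal(a$class, b$class)
  }
})

test_that("intratumor heterogeneity fraction excludes unlabelled records", {
  expect_equal(ith_fraction(c(rep("SUBCLONAL", 3), rep("CLONAL", 7))), 0.3)
  expect_equal(ith_fraction(rep("CLONAL", 5)), 0.0)
  expect_true(is.na(ith_fraction(rep("UNKNOWN", 4))))
  expect_true(is.na(ith_fraction(character(0))))
  x <- c("SUBCLONAL", "CLONAL", "UNKNOWN")
  expect_equal(ith_fraction(rep(x, 5)), ith_fraction(x))
})

test_that("Haldane-Anscombe odds ratios match hand calculations", {
  expect_equal(odds_ratio_haldane(matrix(c(10, 10, 10, 10), 2))$or, 1.0)
  # any zero cell adds 0.5 to all four cells
  r <- odds_ratio_haldane(matrix(c(5, 0, 3, 7), 2, byrow = TRUE))
  expect_true(r$corrected)
  expect_equal(r$or, (5.5 * 7.5) / (0.5 * 3.5))
  expect_equal(round(r$or, 3), 23.571)
  # reciprocal-table product is 1 on zero-free tables
  set.seed(2)
  for (i in 1:20) {
    t <- matrix(sample(1:50, 4, TRUE), 2)
    expect_equal(odds_ratio_haldane(t)$or *
                   odds_ratio_haldane(t[2:1, ])$or, 1.0)
  }
  # degenerate flag on an all-zero row
  expect_true(odds_ratio_haldane(matrix(c(0, 0, 3, 7), 2, byrow = TRUE))$degenerate)
})

test_that("oncogenic vs passenger proportions give the depletion OR", {
  or <- odds_ratio_from_proportions(0.291, 0.569)
  expect_equal(round(or, 2), 0.31)
})

test_that("per-patient clonal/subclonal ORs point the right way", {
  # every subclonal SV neoantigenic, no clonal one: OR > 1 (finite)
  d1 <- data.frame(patient = "p1",
                   clonality = rep(c("SUBCLONAL", "CLONAL"), each = 5),
                   neoantigenic = rep(c(TRUE, FALSE), each = 5))
  r1 <- clonal_subclonal_or(d1)
  expect_gt(r1$per_patient$or, 1)
  expect_true(is.finite(r1$per_patient$or))
  # equal proportions in both classes: OR = 1
  d2 <- data.frame(patient = "p2",
                   clonality = rep(c("SUBCLONAL", "CLONAL"), each = 4),
                   neoantigenic = rep(c(TRUE, FALSE), 4))
  expect_equal(clonal_subclonal_or(d2)$per_patient$or, 1)
  # patients lacking one clonality class are skipped with a reason
  d3 <- data.frame(patient = "p3", clonality = "CLONAL", neoantigenic = TRUE)
  r3 <- clonal_subclonal_or(d3)
  expect_equal(nrow(r3$per_patient), 0L)
  expect_equal(r3$skipped$patient, "p3")
})

test_that("simulated subclonal enrichment is recovered at cohort scale", {
  spec <- sim_spec(seed = 31)
  sim <- simulate_cohort(spec)
  res <- clonal_subclonal_or(sim$sv_table)
  expect_equal(nrow(res$per_patient) + nrow(res$skipped),
               spec$cohort$n_patients)
  expect_gt(res$median_or, 1.7)
  expect_lt(res$median_or, 2.3)
  expect_lt(res$p_value, 0.01)
  # null case: true OR = 1
  spec0 <- sim_spec(seed = 32)
  spec0$cohort$subclonal_or <- 1.0
  res0 <- clonal_subclonal_or(simulate_cohort(spec0)$sv_table)
  expect_gt(res0$median_or, 0.8)
  expect_lt(res0$median_or, 1.25)
})

test_that("logistic depletion model: intercept-only closed form", {
  set.seed(4)
  y <- rbinom(40, 1, 0.3)
  d <- data.frame(X1 = 0, X2 = 0, X3 = 0, y = y)
  fit <- depletion_logistic(d)
  expect_equal(unname(fit$coefficients["b0"]), qlogis(mean(y)),
               tolerance = 1e-6)
  expect_equal(unname(fit$coefficients[c("b1", "b2", "b3")]), rep(0, 3))
  expect_true(fit$converged)
})

test_that("logistic parameter recovery at n = 5000", {
  spec <- sim_spec(seed = 41)
  sim <- simulate_cohort(spec)
  d <- sim$sv_table[seq_len(5000), ]
  fit <- depletion_logistic(d)
  truth <- spec$cohort$beta
  for (i in 1:4) {
    est <- fit$coefficients[i]; se <- fit$se[i]
    expect_lt(abs(est - truth[i]), 3 * se)
  }
  expect_true(fit$converged)
  expect_lt(fit$wald_p, 0.001)     # b1 = -1.2 is well separated from 0
})

test_that("toy fit matches a brute-force likelihood grid to 2 d.p.", {
  set.seed(12)
  d <- data.frame(X1 = rep(c(0, 1), 10), X2 = 0, X3 = rep(c(0, 0, 1, 1), 5))
  eta <- -0.4 + 0.9 * d$X1 - 0.7 * d$X3
  d$y <- rbinom(20, 1, plogis(eta))
  fit <- depletion_logistic(d)
  # independent MLE: coarse grid over (b0, b1, b3) on a hand-written
  # likelihood, then Nelder-Mead refinement from the grid optimum
  loglik <- function(b) {
    p <- plogis(b[1] + b[2] * d$X1 + b[3] * d$X3)
    sum(d$y * log(p) + (1 - d$y) * log(1 - p))
  }
  coarse <- as.matrix(expand.grid(b0 = seq(-3, 3, 0.25),
                                  b1 = seq(-3, 3, 0.25),
                                  b3 = seq(-3, 3, 0.25)))
  lls <- apply(coarse, 1, loglik)
  start <- coarse[which.max(lls), ]
  opt <- optim(start, function(b) -loglik(b))
  expect_equal(unname(fit$coefficients[c("b0", "b1", "b3")]),
               unname(opt$par), tolerance = 0.01)
})

test_that("perfect separation is flagged as non-converged", {
  d <- data.frame(X1 = rep(c(0, 1), each = 10), X2 = 0, X3 = 0,
                  y = rep(c(0, 1), each = 10))
  fit <- depletion_logistic(d)
  expect_false(fit$converged)
})

test_that("burden metrics integrate SV neoantigens with the 323 threshold", {
  b <- burdens(200, 50, 100)
  expect_equal(b$TNB, 250); expect_equal(b$SVNB, 100); expect_equal(b$GANB, 350)
  expect_false(b$TNB_high); expect_true(b$GANB_high); expect_true(b$rescued)
  z <- burdens(0, 0, 0)
  expect_equal(z$GANB, 0); expect_false(z$rescued); expect_false(z$GANB_high)
  nosv <- burdens(400, 0, 0)
  expect_equal(nosv$GANB, nosv$TNB)
  expect_false(nosv$rescued)
  # boundary is strict: exactly 323 is not high
  expect_false(burdens(323, 0, 0)$TNB_high)
  expect_true(burdens(324, 0, 0)$TNB_high)
  # properties: GANB >= TNB; rescued implies SVNB > threshold - TNB
  set.seed(6)
  for (i in 1:25) {
    x <- burdens(sample(0:400, 1), sample(0:50, 1), sample(0:300, 1))
    expect_gte(x$GANB, x$TNB)
    if (x$rescued) expect_gt(x$SVNB, 323 - x$TNB)
  }
})
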