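fixture_beta <- function() {
  read_beta_matrix(system.file("extdata", "beta_10cpg.tsv", package = "driftclock"))
}
fixture_ann <- function() {
  read_probe_annotation(
    system.file("extdata", "probe_annotation_10cpg.csv", package = "driftclock")
  )
}

test_that("packaged 10-CpG fixture filters to the documented removals", {
  res <- filter_probes(fixture_beta(), fixture_ann())
  rep <- res$report
  expect_equal(rep$n_input, 10L)
  expect_equal(rep$n_removed_snp, 2L)
  expect_equal(rep$n_removed_xy, 1L)
  expect_equal(rep$n_removed_crossreactive, 1L)
  expect_equal(rep$n_removed_composition, 0L)
  expect_equal(rep$n_retained, 6L)
  expect_equal(nrow(res$beta), 6L)
  # counts partition the input
  expect_equal(rep$n_input,
               rep$n_retained + rep$n_removed_snp + rep$n_removed_xy +
                 rep$n_removed_crossreactive + rep$n_removed_composition)
})

test_that("permissive thresholds make the filter an identity, and it is idempotent", {
  ann <- fixture_ann()
  ann$cross_reactive <- FALSE
  ann$chromosome <- "1"
  res <- filter_probes(fixture_beta(), ann, maf_threshold = 1.0)
  expect_identical(res$beta, fixture_beta())

  res1 <- filter_probes(fixture_beta(), fixture_ann())
  res2 <- filter_probes(res1$beta, fixture_ann())
  expect_identical(res2$beta, res1$beta)
  expect_equal(res2$report$n_retained, res1$report$n_retained)
})

test_that("removal categories follow first-match order on all flag combinations", {
  # enumerate every combination of (SNP, XY, cross-reactive) and check the
  # attribution is the first matching rule in the fixed order
  combos <- expand.grid(snp = c(FALSE, TRUE), xy = c(FALSE, TRUE),
                        xr = c(FALSE, TRUE))
  ann <- tibble::tibble(
    cpg_id = sprintf("cg%03d", seq_len(nrow(combos))),
    chromosome = ifelse(combos$xy, "X", "1"),
    snp_maf = ifelse(combos$snp, 0.05, NA_real_),
    cross_reactive = combos$xr,
    region_class = "other"
  )
  beta <- make_beta(matrix(0.5, nrow(combos), 3), cpgs = ann$cpg_id)
  rep <- filter_probes(beta, ann)$report
  expected <- ifelse(combos$snp, "snp",
                     ifelse(combos$xy, "xy",
                            ifelse(combos$xr, "cross_reactive", "retained")))
  for (i in seq_len(nrow(combos))) {
    if (expected[i] == "retained") {
      expect_false(ann$cpg_id[i] %in% unlist(rep$removed_ids))
    } else {
      expect_true(ann$cpg_id[i] %in% rep$removed_ids[[expected[i]]])
    }
  }
  # the XY + cross-reactive CpG is counted once, under XY
  both <- ann$cpg_id[combos$xy & combos$xr & !combos$snp]
  expect_true(all(both %in% rep$removed_ids$xy))
  expect_false(any(both %in% rep$removed_ids$cross_reactive))
})

test_that("strict mode errors on unannotated CpGs, lenient warns and keeps", {
  beta <- make_beta(matrix(0.5, 2, 3), cpgs = c("cg0000001", "unknown_cpg"))
  expect_error(filter_probes(beta, fixture_ann()), "unknown_cpg")
  expect_warning(res <- filter_probes(beta, fixture_ann(), strict = FALSE),
                 "missing from annotation")
  expect_true("unknown_cpg" %in% rownames(res$beta))
})

test_that("composition DMPs implement the union rule and its edge cases", {
  set.seed(31)
  beta <- make_beta(matrix(rbeta(200 * 8, 5, 5), 200, 8))
  # a CpG with means 0.30 vs 0.45 clears the 10% delta rule whatever its p
  beta[1, ] <- c(rep(0.30, 4), rep(0.45, 4))
  groups <- rep(c("CD4", "CD8"), each = 4)
  expect_true(rownames(beta)[1] %in% composition_dmps(beta, groups))
  tab <- attr(composition_dmps(beta, groups), "table")
  expect_equal(tab$delta[1], 0.15)
  # identical groups select nothing
  same <- make_beta(cbind(matrix(rbeta(50 * 3, 2, 2), 50, 3),
                          matrix(rbeta(50 * 3, 2, 2), 50, 3)))
  same[, 4:6] <- same[, 1:3]
  expect_length(composition_dmps(same, rep(c("a", "b"), each = 3)), 0L)
  # symmetry in group labels
  s1 <- composition_dmps(beta, groups)
  s2 <- composition_dmps(beta, rev(groups))
  expect_setequal(as.character(s1), as.character(s2))
  # errors
  expect_error(composition_dmps(beta, rep("CD4", 8)), "two group levels")
  expect_error(composition_dmps(beta[, 1:3], c("a", "a", "b")), ">= 2 samples")
})

test_that("raising delta or lowering alpha never enlarges the composition set", {
  set.seed(12)
  beta <- make_beta(matrix(rbeta(500 * 10, 2, 2), 500, 10))
  beta[1:20, 6:10] <- pmin(beta[1:20, 6:10] + 0.15, 1)
  groups <- rep(c("x", "y"), each = 5)
  base <- composition_dmps(beta, groups, delta = 0.10, alpha = 0.05)
  tighter_delta <- composition_dmps(beta, groups, delta = 0.20, alpha = 0.05)
  tighter_alpha <- composition_dmps(beta, groups, delta = 0.10, alpha = 0.01)
  expect_true(all(tighter_delta %in% base))
  expect_true(all(tighter_alpha %in% base))
})

test_that("planted composition CpGs are recovered with controlled FDR", {
  n_null <- 5000L
  recovered <- numeric(0)
  fdr <- numeric(0)
  for (s in 1:20) {
    set.seed(400 + s)
    mu <- runif(n_null + 50, 0.2, 0.7)
    beta <- mu + matrix(rnorm((n_null + 50) * 12, 0, 0.03), n_null + 50, 12)
    beta[1:50, 7:12] <- beta[1:50, 7:12] + 0.2
    beta <- make_beta(pmin(pmax(beta, 0), 1))
    planted <- rownames(beta)[1:50]
    sel <- composition_dmps(beta, rep(c("CD4", "CD8"), each = 6),
                            delta = 0.10, alpha = 0.05)
    recovered <- c(recovered, sum(planted %in% sel))
    tab <- attr(sel, "table")
    null_sig <- sum(tab$p_adj[-(1:50)] < 0.05)
    fdr <- c(fdr, null_sig / max(1, sum(tab$p_adj < 0.05)))
  }
  expect_true(all(recovered >= 48))
  expect_lt(mean(fdr), 0.05)
})

test_that("welch fallback agrees with moderated testing on strong effects", {
  set.seed(5)
  beta <- make_beta(matrix(rbeta(100 * 12, 5, 5), 100, 12))
  beta[1:10, 7:12] <- pmin(beta[1:10, 7:12] + 0.35, 1)
  groups <- rep(c("a", "b"), each = 6)
  s_mod <- composition_dmps(beta, groups)
  s_wel <- composition_dmps(beta, groups, method = "welch")
  expect_true(all(rownames(beta)[1:10] %in% s_mod))
  expect_true(all(rownames(beta)[1:10] %in% s_wel))
})
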