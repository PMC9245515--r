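test_that("spectral-count normalization scales to mean file depth", {
  m <- matrix(c(3, 7, 6, 14), 2, 2,
              dimnames = list(c("p1", "p2"), c("f1", "f2")))
  # equal totals: identity up to the global constant
  eq <- matrix(c(5, 5, 5, 5), 2, 2, dimnames = dimnames(m))
  expect_equal(unclass(normalize_spectral_counts(eq)), eq,
               ignore_attr = TRUE)
  # a protein with 3 counts in a file of half-average depth normalizes to ~6
  half <- matrix(c(3, 27, 10, 50), 2, 2,
                 dimnames = list(c("p1", "p2"), c("shallow", "deep")))
  norm <- normalize_spectral_counts(half)
  expect_equal(norm["p1", "shallow"], 3 * mean(c(30, 60)) / 30)
  z <- matrix(c(0, 0, 1, 2), 2, 2, dimnames = list(NULL, c("bad", "ok")))
  expect_error(normalize_spectral_counts(z), "bad")
  # heatmap eligibility threshold
  nm <- matrix(c(1, 4, 2, 5), 2, 2, dimnames = list(c("lo", "hi"), NULL))
  expect_equal(rownames(heatmap_eligible(nm, 3)), "hi")
})

test_that("fold change maps ratios to percent decreases", {
  m <- matrix(c(100, 100, 68, 68, 93, 93), 1, 6,
              dimnames = list("COL1", NULL))
  fc7 <- fold_change(m, 3:4, 1:2)
  expect_equal(fc7$ratio, 0.68)
  expect_equal(fc7$percent_change, 32)
  fc30 <- fold_change(m, 5:6, 1:2)
  expect_equal(fc30$ratio, 0.93)
  expect_equal(fc30$percent_change, 7, tolerance = 1e-9)
  same <- fold_change(m, 1:2, 1:2)
  expect_equal(same$ratio, 1)
  zero <- fold_change(matrix(c(0, 0, 5, 5), 1, 4), 3:4, 1:2)
  expect_true(is.na(zero$ratio))
})

test_that("heatmap matrix is row-standardized and clipped", {
  m <- matrix(c(1, 2, 3), 1, 3)
  z <- heatmap_matrix(m)
  expect_equal(as.numeric(z), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(heatmap_matrix(matrix(5, 1, 4)), matrix(0, 1, 4))
  wide <- heatmap_matrix(matrix(c(0, 0, 0, 100), 1, 4))
  expect_true(all(wide >= -2 & wide <= 2))
  expect_error(heatmap_matrix(matrix(1, 2, 1)), ">= 2 columns")
})

feature_row <- function(state, area, condition = "sham", replicate = 1,
                        position = 10, peptidoform = paste0("f_", state)) {
  data.frame(peptidoform = peptidoform, chain_id = "c", position = position,
             state = state, condition = condition, replicate = replicate,
             area = area, ambiguous = FALSE, stringsAsFactors = FALSE)
}

test_that("site occupancy is the MS1 area fraction per state", {
  f <- rbind(feature_row("unmod", 900), feature_row("HyP", 100))
  occ <- site_occupancy(f, "c", 10)
  expect_equal(occ$mean[occ$state == "HyP"], 10)
  expect_equal(sum(occ$mean), 100)
  # invariance to rescaling all areas in a replicate
  f2 <- f
  f2$area <- f2$area * 7.3
  expect_equal(site_occupancy(f2, "c", 10)$mean, occ$mean)
  # ambiguous-localization rows are excluded by default, apportioned on
  # request
  f3 <- rbind(f, {
    r <- feature_row("HyK|G-HyK", 200)
    r$ambiguous <- TRUE
    r
  })
  occ3 <- site_occupancy(f3, "c", 10)
  expect_equal(sum(occ3$mean), 100)
  expect_false("HyK" %in% occ3$state[occ3$mean > 0])
  occ4 <- site_occupancy(f3, "c", 10, apportion_equal = TRUE)
  expect_equal(occ4$mean[occ4$state == "HyK"],
               occ4$mean[occ4$state == "G-HyK"])
  expect_equal(sum(occ4$mean), 100)
})

test_that("not-detected replicates propagate as ND, never as zero", {
  f <- rbind(feature_row("unmod", 0), feature_row("HyP", 0),
             feature_row("unmod", 60, replicate = 2),
             feature_row("HyP", 40, replicate = 2))
  occ <- site_occupancy(f, "c", 10)
  expect_equal(occ$n_replicates, c(1L, 1L))
  expect_equal(occ$mean[occ$state == "HyP"], 40)
  # all replicates empty: the record is ND with NA percents
  f0 <- rbind(feature_row("unmod", 0), feature_row("HyP", 0))
  occ0 <- site_occupancy(f0, "c", 10)
  expect_true(all(occ0$nd))
  expect_true(all(is.na(occ0$mean)))
})

test_that("cluster occupancy bounds individual site occupancies", {
  # two sites on one peptidoform set: forms 00, 10, 01, 11
  mk <- function(pf, s1, s2, area) {
    rbind(feature_row(s1, area, position = 10, peptidoform = pf),
          feature_row(s2, area, position = 13, peptidoform = pf))
  }
  f <- rbind(mk("p00", "unmod", "unmod", 500), mk("p10", "HyP", "unmod", 200),
             mk("p01", "unmod", "HyP", 200), mk("p11", "HyP", "HyP", 100))
  cl <- cluster_occupancy(f, "c", c(10, 13))
  expect_equal(cl$mean[cl$state == "modified"], 50)
  s10 <- site_occupancy(f[f$position == 10, ], "c", 10)
  expect_gte(cl$mean[cl$state == "modified"],
             s10$mean[s10$state == "HyP"])
  # all unmodified: zero
  f0 <- rbind(mk("q", "unmod", "unmod", 100))
  cl0 <- cluster_occupancy(f0, "c", c(10, 13))
  expect_equal(cl0$mean[cl0$state == "modified"], 0)
})

test_that("planted cluster occupancy is recovered within 5 points", {
  cfg <- sim_config(seed = 11, noise_cv = 0.10)
  hits <- numeric(50)
  for (r in 1:50) {
    truth <- data.frame(chain_id = "c", position = c(8, 8),
                        residue = "P", state = c("HyP", "unmod"),
                        condition = "sham", true_pct = c(25, 75))
    ch <- collagen_chain("c", "AAAGAAGPPGAAK")
    f <- simulate_features(ch, truth, cfg, seed = 5000 + r)
    occ <- site_occupancy(f, "c", 8)
    hits[r] <- occ$mean[occ$state == "HyP"]
  }
  expect_lt(abs(mean(hits) - 25), 5)
})

test_that("one-way ANOVA matches the sums-of-squares oracle", {
  vals <- c(1, 2, 1, 2, 1, 2, 9, 10)
  grp <- rep(c("a", "b", "c", "d"), each = 2)
  res <- anova_oneway(vals, grp)
  expect_true(res$testable)
  expect_equal(res$F, oracle_anova_F(vals, grp), tolerance = 1e-9)
  expect_lt(res$p, 0.05)
  # identical values across groups: p = 1 by convention
  flat <- anova_oneway(rep(5, 8), grp)
  expect_equal(flat$p, 1)
  expect_false(flat$significant)
  # insufficient replication is flagged untestable
  one <- anova_oneway(c(1, 2), c("a", "b"))
  expect_false(one$testable)
})

test_that("a planted monotone increase is detected by ANOVA with power", {
  # GG-HyK rising 2% -> 15% across conditions, small area noise
  cfg <- sim_config(seed = 13, noise_cv = 0.05)
  ch <- collagen_chain("c", "AAAGAPGAKGAAR")
  prof <- c(sham = 2, `7DPA` = 5, `14DPA` = 10, `30DPA` = 15)
  sig <- 0L
  n_runs <- 100L
  for (r in seq_len(n_runs)) {
    truth <- do.call(rbind, lapply(names(prof), function(cond) {
      data.frame(chain_id = "c", position = 9, residue = "K",
                 state = c("GG-HyK", "HyK"), condition = cond,
                 true_pct = c(prof[[cond]], 100 - prof[[cond]]))
    }))
    f <- simulate_features(ch, truth, cfg, seed = 20000 + r)
    occ <- site_occupancy(f, "c", 9)
    reps <- attr(occ, "replicates")
    vals <- unlist(lapply(reps, function(m) m[, "GG-HyK"]))
    grp <- rep(names(reps), vapply(reps, nrow, integer(1)))
    a <- anova_oneway(vals, grp)
    if (isTRUE(a$significant)) sig <- sig + 1L
  }
  expect_gte(sig / n_runs, 0.90)
})

test_that("run_quant summarizes occupancy with ANOVA flags end to end", {
  cfg <- sim_config(seed = 2, helical_triplets = 24, n_k_sites = 2,
                    n_p_sites = 2)
  ch <- generate_chain(cfg)
  truth <- plant_sites(ch, cfg)
  feats <- simulate_features(ch, truth, cfg)
  out <- run_quant(feats)
  expect_true(all(c("anova_p", "significant") %in% names(out)))
  sums <- tapply(out$mean, paste(out$position, out$condition), sum)
  expect_true(all(abs(sums - 100) < 0.1, na.rm = TRUE))
  # empty feature table warns and returns empty
  expect_warning(res <- run_quant(feats[0, ]), "empty")
  expect_equal(nrow(res), 0)
})
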