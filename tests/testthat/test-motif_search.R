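make_enum_case <- function() {
  # GAAGPPGPKGDR digested out of a chain giving 2 eligible P... build a
  # peptide with exactly 2 P and 1 internal G-X-K lysine and no M
  ch <- collagen_chain("c", "AAAKGAPGPKGDRGAAK")
  ann <- annotate_motifs(ch)
  peps <- digest_chain(ch, 2)
  pep <- peps[peps$sequence == "GAPGPKGDR", ]
  list(chain = ch, ann = ann, pep = pep)
}

test_that("peptidoform enumeration matches the closed-form state count", {
  cs <- make_enum_case()
  forms <- enumerate_peptidoforms(cs$pep, cs$ann, search_params())
  # 2 P x {unmod, HyP} and 1 internal GXK-K x 4 states = 16
  expect_equal(nrow(forms), 16)
  expect_equal(anyDuplicated(forms$label), 0)
  # no eligible residues: the peptide itself only
  ch2 <- collagen_chain("c2", "AVLDEK")
  f2 <- enumerate_peptidoforms(digest_chain(ch2, 0), annotate_motifs(ch2),
                               search_params())
  expect_equal(nrow(f2), 1)
  expect_equal(f2$mod_string, "")
  # mod cap 1: unmodified + 2 single-HyP + 3 single-K states = 6
  f3 <- enumerate_peptidoforms(cs$pep, cs$ann,
                               search_params(max_dynamic_mods = 1))
  expect_equal(nrow(f3), 6)
})

test_that("enumeration counts equal brute force across random cases", {
  set.seed(42)
  for (i in 1:6) {
    npos <- sample(1:5, 1)
    seqres <- c(sample(c("A", "G", "P", "M", "S"), 10, replace = TRUE), "K")
    seq <- paste(seqres, collapse = "")
    ch <- collagen_chain("r", paste0("AAAK", seq))
    ann <- annotate_motifs(ch)
    peps <- digest_chain(ch, 4)
    pep <- peps[peps$sequence == seq, ][1, ]
    if (is.na(pep$start)) next
    cap <- sample(1:4, 1)
    forms <- enumerate_peptidoforms(pep, ann,
                                    search_params(max_dynamic_mods = cap))
    # option counts per eligible residue, mirroring the motif rules
    gxk <- ann$position[ann$motif_class == "GXK_LYS"]
    res <- strsplit(seq, "")[[1]]
    n_opts <- integer(0)
    for (j in seq_along(res)) {
      chainpos <- pep$start + j - 1L
      if (res[j] == "P") n_opts <- c(n_opts, 1L)
      else if (res[j] == "M") n_opts <- c(n_opts, 1L)
      else if (res[j] == "K" && chainpos %in% gxk) {
        n_opts <- c(n_opts, if (j == length(res)) 1L else 3L)
      }
    }
    expect_equal(nrow(forms), oracle_form_count(n_opts, cap),
                 info = paste("case", i, seq, "cap", cap))
  }
})

test_that("enumeration guard trips on oversized state spaces", {
  ch <- collagen_chain("big", paste0(strrep("GPP", 25), "K"))
  ann <- annotate_motifs(ch)
  pep <- data.frame(chain_id = "big", start = 1,
                    end = nchar(chain_sequence(ch)),
                    sequence = chain_sequence(ch))
  expect_error(
    enumerate_peptidoforms(pep, ann, search_params(enum_guard = 1e4)),
    "enumeration guard")
})

test_that("glycosylated lysine is excluded from the peptide C-terminus", {
  ch <- collagen_chain("c", "AAAKGAPGPKGAAK")
  ann <- annotate_motifs(ch)
  peps <- digest_chain(ch, 0)
  pep <- peps[peps$sequence == "GAPGPK", ]
  forms <- enumerate_peptidoforms(pep, ann, search_params())
  kmods <- grep("6:", forms$mod_string, value = TRUE, fixed = TRUE)
  expect_true(all(grepl("6:HyK", kmods, fixed = TRUE)))
  forms2 <- enumerate_peptidoforms(pep, ann,
                                   search_params(allow_cterm_glyco = TRUE))
  expect_gt(nrow(forms2), nrow(forms))
})

test_that("theoretical b/y ions satisfy complementarity and carry deltas", {
  d <- setNames(modification_table()$delta_mass, modification_table()$name)
  seq <- "GAPGPKGDR"
  ions <- theoretical_ions(seq, "", max_charge = 1)
  n <- nchar(seq)
  M <- peptide_mono_mass(seq)
  b <- ions$mz[grepl("^b", ions$ion)]
  y <- ions$mz[grepl("^y", ions$ion)]
  # b_i + y_(n-i) is constant: neutral mass + water-free complement terms
  sums <- b + rev(y)
  expect_true(all(abs(sums - sums[1]) < 1e-9))
  expect_equal(sums[1], M + 2 * 1.00727646688, tolerance = 1e-8)
  # y1 of a K-terminated peptide
  yk <- theoretical_ions("GAPGK", "", max_charge = 1)
  expect_equal(yk$mz[yk$ion == "y1"], 147.112804, tolerance = 1e-5)
  # a HyP at position 3 shifts exactly the fragments containing position 3
  i0 <- theoretical_ions("GAPGPK", "", max_charge = 1)
  i1 <- theoretical_ions("GAPGPK", "3:HyP", max_charge = 1)
  shift <- i1$mz - i0$mz
  bnum <- as.integer(sub("[by]", "", i0$ion))
  contains <- ifelse(grepl("^b", i0$ion), bnum >= 3, bnum >= 6 - 3 + 1)
  expect_equal(shift > 1e-9, contains)
  expect_true(all(abs(shift[contains] - d[["HyP"]]) < 1e-9))
})

test_that("PSM scoring is dominated by the generating peptidoform", {
  cs <- make_enum_case()
  forms <- enumerate_peptidoforms(cs$pep, cs$ann, search_params())
  truth <- forms[forms$mod_string == "5:HyP;6:GG-HyK", ]
  ions <- theoretical_ions(truth$sequence, truth$mod_string, max_charge = 1)
  spectrum <- list(id = "s", precursor_mz = mass_to_mz(truth$mass, 2),
                   charge = 2,
                   peaks = cbind(mz = sort(ions$mz),
                                 intensity = rep(1000, nrow(ions))))
  scores <- vapply(seq_len(nrow(forms)), function(i) {
    th <- theoretical_ions(forms$sequence[i], forms$mod_string[i],
                           max_charge = 1)
    score_psm(spectrum, th, 20)$score
  }, numeric(1))
  expect_equal(which.max(scores), which(forms$mod_string == truth$mod_string))
  # empty peak list scores zero
  empty <- list(id = "e", peaks = matrix(numeric(0), ncol = 2))
  expect_equal(score_psm(empty, ions, 20)$score, 0)
})

test_that("true peptidoform ranks first among siblings under 10% dropout", {
  cs <- make_enum_case()
  forms <- enumerate_peptidoforms(cs$pep, cs$ann, search_params())
  truth <- forms[forms$mod_string == "5:HyP;6:GG-HyK", ]
  cfg <- sim_config(seed = 7, dropout = 0.10)
  wins <- 0L
  n_trials <- 200L
  theo <- lapply(seq_len(nrow(forms)), function(i) {
    theoretical_ions(forms$sequence[i], forms$mod_string[i], max_charge = 1)
  })
  for (t in seq_len(n_trials)) {
    sp <- simulate_spectra(truth, cfg, seed = 1000 + t)[[1]]
    scores <- vapply(theo, function(th) score_psm(sp, th, 20)$score,
                     numeric(1))
    truth_i <- which(forms$mod_string == truth$mod_string)
    if (which.max(scores) == truth_i) wins <- wins + 1L
  }
  expect_gte(wins / n_trials, 0.95)
})

test_that("decoy construction reverses sequences and preserves composition", {
  chains <- list(a = collagen_chain("a", "GPKGDR"))
  dec <- make_decoys(chains)
  expect_equal(chain_sequence(dec$DECOY_a), "RDGKPG")
  expect_equal(sort(strsplit(chain_sequence(dec$DECOY_a), "")[[1]]),
               sort(strsplit("GPKGDR", "")[[1]]))
  # a peptide shared between target and decoy is counted as target only
  pal <- list(p = collagen_chain("p", "AAKGAAGAAKAA"))
  idx <- build_search_index(pal, search_params(min_length = 2))
  expect_false(any(idx$is_decoy &
                     idx$sequence %in% idx$sequence[!idx$is_decoy]))
  expect_true("AAK" %in% idx$sequence[!idx$is_decoy])
})

test_that("q-values are monotone and the hand-computable case passes", {
  psms <- data.frame(
    spectrum_id = paste0("s", 1:6), chain_id = "c", start = 1, end = 5,
    sequence = "AAAAA", mod_string = "", label = paste0("f", 1:6),
    score = c(10, 9, 8, 7, 6, 5), n_matched = 5,
    is_decoy = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  )
  out <- fdr_filter(psms, 0.01, keep_decoys = TRUE)
  expect_equal(nrow(out), 4)
  expect_true(all(!out$is_decoy))
  expect_true(all(out$q_value == 0))
  # all decoys outscoring all targets: nothing passes
  psms2 <- psms
  psms2$is_decoy <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_equal(nrow(fdr_filter(psms2, 0.01)), 0)
  # q monotone non-increasing in score
  psms3 <- psms
  psms3$is_decoy <- c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE)
  out3 <- fdr_filter(psms3, 1, keep_decoys = TRUE)
  o <- order(out3$score, decreasing = TRUE)
  expect_true(all(diff(out3$q_value[o]) >= 0))
  expect_error(fdr_filter(psms[psms$is_decoy, ], 0.01), "no target")
})

test_that("search is deterministic and competition picks one PSM per spectrum", {
  cfg <- sim_config(seed = 3, helical_triplets = 24, n_spectra = 30,
                    n_k_sites = 2, n_p_sites = 2)
  ds <- simulate_dataset(cfg)
  params <- sim_search_params(cfg)
  idx <- build_search_index(list(ds$chain), params)
  p1 <- search_spectra(ds$spectra, idx, params)
  p2 <- search_spectra(ds$spectra, idx, params)
  expect_identical(p1, p2)
  expect_equal(anyDuplicated(p1$spectrum_id), 0)
})
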