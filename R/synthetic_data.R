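#' Simulation configuration
#'
#' Bundles every parameter of the synthetic collagen study: one chain
#' shaped like a fibrillar procollagen (signal peptide + N-propeptide +
#' (Gly-Xaa-Yaa)n helical core + C-propeptide), planted per-site
#' modification-state occupancy profiles over four conditions
#' (sham and 7/14/30 days post-amputation) with two biological replicates
#' each, multiplicative log-normal noise on MS1 areas, and HCD b/y
#' spectra with peak dropout and random noise peaks.
#'
#' @param seed Global seed; per-component child seeds are derived from it
#'   deterministically, so chains, features and spectra can be regenerated
#'   independently.
#' @param helical_triplets Number of Gly-Xaa-Yaa triplets in the core.
#' @param signal_length,n_propeptide_length,c_propeptide_length Segment
#'   lengths in residues.
#' @param conditions Condition labels.
#' @param replicates Biological replicates per condition.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal area noise (fraction).
#' @param dropout Per-ion peak dropout probability in simulated spectra.
#' @param noise_peaks Number of uniform random noise peaks per spectrum.
#' @param fragment_jitter_ppm Half-width of the uniform fragment m/z
#'   jitter (ppm).
#' @param precursor_jitter_ppm Half-width of the uniform precursor jitter
#'   (ppm).
#' @param n_k_sites,n_p_sites Number of planted lysine-microheterogeneity
#'   and 3-hydroxyproline occupancy sites.
#' @param n_spectra Spectra in the simulated MGF.
#' @param base_area Median MS1 base abundance (arbitrary units).
#' @param detection_floor Areas below this fraction of the site base
#'   abundance are zeroed (simulating non-detection).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, helical_triplets = 100,
                       signal_length = 22, n_propeptide_length = 40,
                       c_propeptide_length = 40,
                       conditions = c("sham", "7DPA", "14DPA", "30DPA"),
                       replicates = 2, noise_cv = 0.10, dropout = 0.10,
                       noise_peaks = 20, fragment_jitter_ppm = 10,
                       precursor_jitter_ppm = 5,
                       n_k_sites = 4, n_p_sites = 4, n_spectra = 200,
                       base_area = 1e6, detection_floor = 0) {
  stopifnot(helical_triplets > 0, signal_length > 0,
            n_propeptide_length > 0, c_propeptide_length > 0,
            noise_cv >= 0, dropout >= 0, dropout <= 1, replicates >= 1)
  structure(as.list(environment()), class = "sim_config")
}

# Derive a stable child seed (< 2^31) from the global seed and a
# component name, so each stage has its own reproducible stream.
derive_seed <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)) * 131)
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# collagen-like residue frequencies for the Xaa and Yaa slots
XAA_FREQ <- c(P = .30, A = .18, S = .08, E = .08, D = .06, L = .06,
              V = .05, N = .04, Q = .05, F = .03, T = .04, I = .03)
YAA_FREQ <- c(P = .45, A = .15, Q = .08, E = .07, S = .07, T = .06,
              V = .05, L = .04, M = .03)
NONHELICAL_FREQ <- c(A = .12, S = .10, T = .08, V = .08, L = .09, I = .05,
                     E = .09, D = .07, Q = .07, N = .05, F = .05, Y = .04,
                     H = .03, W = .01, M = .03, G = .04)

#' Generate a collagen-like chain
#'
#' Builds signal peptide + N-propeptide + (Gly-Xaa-Yaa)n core +
#' C-propeptide, with proline enriched in both Xaa and Yaa slots,
#' periodic lysine in the Yaa slot (creating G-X-K motifs) and arginine
#' placed so that a tryptic cleavage site occurs at least every 40
#' residues. Deterministic for a fixed seed.
#'
#' @param config A [sim_config()].
#' @param id Chain identifier.
#' @return A `CollagenChain` with segment intervals set.
#' @export
generate_chain <- function(config = sim_config(), id = "SYNCOL1A1") {
  with_seed(derive_seed(config$seed, "chain"), {
    draw <- function(n, freq) sample(names(freq), n, replace = TRUE, prob = freq)
    nonhel <- function(n, period) {
      r <- draw(n, NONHELICAL_FREQ)
      r[seq_along(r) %% period == 0] <- "R" # guaranteed tryptic sites
      r
    }
    signal <- nonhel(config$signal_length, 12)
    npro <- nonhel(config$n_propeptide_length, 15)
    cpro <- nonhel(config$c_propeptide_length, 15)
    nt <- config$helical_triplets
    core <- character(3 * nt)
    for (t in seq_len(nt)) {
      x <- draw(1, XAA_FREQ)
      # periodic Yaa lysines (G-X-K motifs), arginines (tryptic sites)
      # and Gly-Pro-Pro triplets (3-HyP-eligible clusters)
      if (t %% 8 == 4) {
        y <- "K"
      } else if (t %% 8 == 0) {
        y <- "R"
      } else if (t %% 8 == 2) {
        x <- "P"
        y <- "P"
      } else {
        y <- draw(1, YAA_FREQ)
      }
      core[(3 * t - 2):(3 * t)] <- c("G", x, y)
    }
    seq <- paste(c(signal, npro, core, cpro), collapse = "")
    ns <- config$signal_length
    np <- config$n_propeptide_length
    nc <- config$c_propeptide_length
    total <- nchar(seq)
    collagen_chain(id, seq, species = "synthetic",
                   signal_peptide = c(1L, ns),
                   n_propeptide = c(ns + 1L, ns + np),
                   c_propeptide = c(total - nc + 1L, total))
  })
}

# occupancy templates (percent per condition) shaped like observed
# lysine-microheterogeneity and 3-HyP dynamics in regenerating heart ECM
default_k_profile <- function(i) {
  templates <- list(
    rbind(sham = c(unmod = 62.44, HyK = 34.82, `G-HyK` = 0, `GG-HyK` = 2.74),
          `7DPA` = c(33.69, 62.96, 0, 3.35),
          `14DPA` = c(52.55, 36.95, 0, 10.50),
          `30DPA` = c(60.09, 24.44, 0, 15.47)),
    rbind(sham = c(unmod = 36.62, HyK = 38.38, `G-HyK` = 16.71, `GG-HyK` = 8.29),
          `7DPA` = c(43.75, 34.81, 17.85, 3.59),
          `14DPA` = c(46.29, 21.13, 31.26, 1.32),
          `30DPA` = c(31.71, 45.72, 20.22, 2.35)),
    rbind(sham = c(unmod = 50.46, HyK = 34.97, `G-HyK` = 12.25, `GG-HyK` = 2.32),
          `7DPA` = c(32.91, 37.13, 29.03, 0.93),
          `14DPA` = c(26.58, 46.12, 24.56, 2.74),
          `30DPA` = c(46.49, 40.69, 11.52, 1.30)),
    rbind(sham = c(unmod = 16.05, HyK = 73.86, `G-HyK` = 1.34, `GG-HyK` = 8.75),
          `7DPA` = c(11.35, 83.40, 0.25, 5.00),
          `14DPA` = c(21.14, 70.60, 0.56, 7.70),
          `30DPA` = c(17.46, 74.25, 1.47, 6.82))
  )
  templates[[(i - 1L) %% length(templates) + 1L]]
}

default_p_profile <- function(i) {
  templates <- list(
    c(sham = 48.73, `7DPA` = 44.03, `14DPA` = 68.96, `30DPA` = 7.23),
    c(sham = 7.55, `7DPA` = 31.49, `14DPA` = 21.21, `30DPA` = 20.50),
    c(sham = 35.37, `7DPA` = 22.82, `14DPA` = 48.10, `30DPA` = 20.12),
    c(sham = 28.87, `7DPA` = 17.57, `14DPA` = 27.63, `30DPA` = 12.76)
  )
  templates[[(i - 1L) %% length(templates) + 1L]]
}

#' Plant modification sites on a generated chain
#'
#' Chooses `n_k_sites` G-X-K lysines and `n_p_sites` Xaa prolines whose
#' Yaa partner is also proline (3-HyP-eligible clusters) inside the
#' mature range, and assigns each a per-condition true occupancy profile.
#' Lysine sites receive a four-state microheterogeneity profile; proline
#' sites a hydroxylated-vs-unmodified split.
#'
#' @param chain A `CollagenChain` from [generate_chain()].
#' @param config A [sim_config()].
#' @return A data.frame (the planted-truth ledger): `chain_id`,
#'   `position`, `residue`, `state`, `condition`, `true_pct`.
#' @export
plant_sites <- function(chain, config = sim_config()) {
  ann <- annotate_motifs(chain)
  mr <- mature_range(chain)
  seq <- chain_sequence(chain)
  with_seed(derive_seed(config$seed, "plant"), {
    kpos <- ann$position[ann$motif_class == "GXK_LYS" &
                           ann$position >= mr[1] & ann$position <= mr[2]]
    ppos <- ann$position[ann$motif_class == "XAA_PRO" &
                           ann$position >= mr[1] & ann$position < mr[2]]
    ppos <- ppos[substring(seq, ppos + 1L, ppos + 1L) == "P"]
    if (length(kpos) < config$n_k_sites) {
      stop("chain has only ", length(kpos), " eligible G-X-K sites")
    }
    if (length(ppos) < config$n_p_sites) {
      stop("chain has only ", length(ppos), " 3-HyP-eligible Gly-Pro-Pro sites")
    }
    kpick <- sort(sample(kpos, config$n_k_sites))
    ppick <- sort(sample(ppos, config$n_p_sites))
    rows <- list()
    for (i in seq_along(kpick)) {
      prof <- default_k_profile(i)
      for (cond in config$conditions) {
        pct <- prof[cond, ]
        rows[[length(rows) + 1L]] <- data.frame(
          chain_id = chain$id, position = kpick[i], residue = "K",
          state = colnames(prof), condition = cond,
          true_pct = as.numeric(pct), stringsAsFactors = FALSE
        )
      }
    }
    for (i in seq_along(ppick)) {
      prof <- default_p_profile(i)
      for (cond in config$conditions) {
        rows[[length(rows) + 1L]] <- data.frame(
          chain_id = chain$id, position = ppick[i], residue = "P",
          state = c("HyP", "unmod"), condition = cond,
          true_pct = c(prof[cond], 100 - prof[cond]),
          stringsAsFactors = FALSE
        )
      }
    }
    truth <- do.call(rbind, rows)
    rownames(truth) <- NULL
    truth
  })
}

#' Simulate an MS1 feature table from a planted-truth ledger
#'
#' For each planted site, condition and replicate, the area of each state
#' is `base abundance x true state fraction x LogNormal noise`, with the
#' log-normal scaled to unit mean and coefficient of variation
#' `noise_cv`. Areas below `detection_floor x base abundance` are zeroed
#' (not detected). With zero noise the recovered occupancy equals the
#' planted occupancy exactly; occupancy estimates are invariant to
#' rescaling all areas of a replicate.
#'
#' @param chain The source `CollagenChain`.
#' @param truth Planted-truth ledger from [plant_sites()].
#' @param config A [sim_config()].
#' @param seed Optional seed override (defaults to the config-derived
#'   feature seed).
#' @return An MS1 feature table suitable for [site_occupancy()].
#' @export
simulate_features <- function(chain, truth, config = sim_config(),
                              seed = NULL) {
  ann <- annotate_motifs(chain)
  ok <- truth$position %in% ann$position[ann$motif_class != "NONE"]
  if (!all(ok)) {
    stop("planted site(s) off-motif: ",
         paste(unique(truth$position[!ok]), collapse = ", "))
  }
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  with_seed(seed %||% derive_seed(config$seed, "features"), {
    sites <- unique(truth[c("chain_id", "position")])
    rows <- list()
    for (s in seq_len(nrow(sites))) {
      base <- config$base_area * stats::rlnorm(1, 0, 0.3)
      tt <- truth[truth$position == sites$position[s], , drop = FALSE]
      for (cond in unique(tt$condition)) {
        tc <- tt[tt$condition == cond, , drop = FALSE]
        for (r in seq_len(config$replicates)) {
          noise <- stats::rlnorm(nrow(tc), -sdlog^2 / 2, sdlog)
          if (config$noise_cv == 0) noise <- rep(1, nrow(tc))
          area <- base * tc$true_pct / 100 * noise
          area[area < config$detection_floor * base] <- 0
          rows[[length(rows) + 1L]] <- data.frame(
            peptidoform = paste0(tc$chain_id, "_", tc$position, "_", tc$state),
            chain_id = tc$chain_id, position = tc$position, state = tc$state,
            condition = cond, replicate = r, area = area,
            ambiguous = FALSE, stringsAsFactors = FALSE
          )
        }
      }
    }
    feats <- do.call(rbind, rows)
    rownames(feats) <- NULL
    feats
  })
}

#' Simulate HCD spectra for a set of peptidoforms
#'
#' Generates b/y peaks at the theoretical m/z values jittered uniformly
#' within half the fragment tolerance, log-normal intensities, per-ion
#' dropout, uniform random noise peaks, and a precursor m/z with uniform
#' jitter. Deterministic for a fixed seed. With zero dropout and no noise
#' peaks the generating peptidoform always outscores its siblings.
#'
#' @param peptidoforms Data.frame with columns `sequence`, `mod_string`,
#'   `mass` (e.g. rows of [enumerate_peptidoforms()] output).
#' @param config A [sim_config()].
#' @param charge Precursor charge applied to all spectra (default 2).
#' @param seed Optional seed override.
#' @return A list of spectra (the [read_mgf()] structure), one per row,
#'   with ids `sim_<row>` carrying a `truth` attribute (the generating
#'   labels).
#' @export
simulate_spectra <- function(peptidoforms, config = sim_config(), charge = 2,
                             seed = NULL) {
  with_seed(seed %||% derive_seed(config$seed, "spectra"), {
    spectra <- vector("list", nrow(peptidoforms))
    for (i in seq_len(nrow(peptidoforms))) {
      ions <- theoretical_ions(peptidoforms$sequence[i],
                               peptidoforms$mod_string[i], max_charge = 1)
      keep <- stats::runif(nrow(ions)) >= config$dropout
      mz <- ions$mz[keep]
      jit <- stats::runif(length(mz), -config$fragment_jitter_ppm / 2,
                          config$fragment_jitter_ppm / 2)
      mz <- mz * (1 + jit * 1e-6)
      int <- stats::rlnorm(length(mz), log(1e4), 0.5)
      if (config$noise_peaks > 0 && length(ions$mz) > 0) {
        nz <- stats::runif(config$noise_peaks,
                           min(ions$mz) * 0.9, max(ions$mz) * 1.1)
        mz <- c(mz, nz)
        int <- c(int, stats::rlnorm(config$noise_peaks, log(1e3), 0.5))
      }
      o <- order(mz)
      pj <- stats::runif(1, -config$precursor_jitter_ppm / 2,
                         config$precursor_jitter_ppm / 2)
      spectra[[i]] <- list(
        id = paste0("sim_", i),
        precursor_mz = mass_to_mz(peptidoforms$mass[i], charge) *
          (1 + pj * 1e-6),
        charge = charge, rt = NA_real_,
        peaks = matrix(c(mz[o], int[o]), ncol = 2,
                       dimnames = list(NULL, c("mz", "intensity")))
      )
    }
    attr(spectra, "truth") <- if ("label" %in% names(peptidoforms)) {
      peptidoforms$label
    } else {
      peptidoforms$sequence
    }
    spectra
  })
}

#' Simulate a complete synthetic dataset
#'
#' Generates the chain, plants occupancy profiles, builds a set of "true"
#' peptidoforms that carry every planted site in its modified state
#' (3-HyP sites are planted together with their hydroxylated Yaa partner,
#' so the positional assignment rule applies), simulates `n_spectra`
#' fragment spectra from them plus unmodified background peptides, and
#' simulates the MS1 feature table. Fully deterministic under the config
#' seed.
#'
#' @param config A [sim_config()].
#' @return A list with `chain`, `truth` (occupancy ledger),
#'   `planted_sites` (data.frame of position/state pairs expected in the
#'   site catalog), `peptidoforms` (the generating forms, one per
#'   spectrum), `spectra`, and `features`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  chain <- generate_chain(config)
  truth <- plant_sites(chain, config)
  ann <- annotate_motifs(chain)
  params <- search_params()
  peps <- digest_chain(chain, max_missed = 2)
  len <- nchar(peps$sequence)
  peps <- peps[len >= params$min_length & len <= 40, , drop = FALSE]

  # planted sites are the modified states with nonzero occupancy in at
  # least one condition
  mod_truth <- truth[truth$state != "unmod", , drop = FALSE]
  any_pos <- tapply(mod_truth$true_pct,
                    paste(mod_truth$position, mod_truth$state), max)
  mod_truth <- mod_truth[any_pos[paste(mod_truth$position,
                                       mod_truth$state)] > 0, , drop = FALSE]
  planted <- unique(mod_truth[c("chain_id", "position", "residue", "state")])
  # one generating peptidoform per planted (site, state)
  gen <- list()
  for (i in seq_len(nrow(planted))) {
    pos <- planted$position[i]
    st <- planted$state[i]
    cover <- peps[peps$start <= pos & peps$end >= pos, , drop = FALSE]
    # glycosylated lysine cannot sit at the peptide C-terminus: generate
    # such forms from a covering peptide with an internal lysine
    if (planted$residue[i] == "K" && st %in% c("G-HyK", "GG-HyK")) {
      cover <- cover[cover$end > pos, , drop = FALSE]
    }
    if (nrow(cover) == 0) next
    pep <- cover[which.min(nchar(cover$sequence)), , drop = FALSE]
    rel <- pos - pep$start + 1L
    mods <- paste0(rel, ":", st)
    if (planted$residue[i] == "P") {
      # plant the Yaa hydroxylation alongside the Xaa site (G-Xaa-HyP)
      yaa <- pos + 1L
      if (yaa <= pep$end &&
          substr(chain_sequence(chain), yaa, yaa) == "P") {
        mods <- paste0(mods, ";", rel + 1L, ":HyP")
      }
    }
    pm <- parse_mod_string(mods)
    mt <- modification_table()
    deltas <- stats::setNames(mt$delta_mass, mt$name)
    mass <- peptide_mono_mass(pep$sequence) +
      sum(strsplit(pep$sequence, "")[[1]] == "C") * deltas[["Carbamidomethyl"]] +
      sum(deltas[pm$name])
    gen[[length(gen) + 1L]] <- data.frame(
      chain_id = pep$chain_id, start = pep$start, end = pep$end,
      sequence = pep$sequence, mod_string = mods, mass = mass,
      label = peptidoform_label(pep$sequence, mods),
      position = pos, state = st, stringsAsFactors = FALSE
    )
  }
  gen <- do.call(rbind, gen)
  # background: unmodified peptides
  with_seed(derive_seed(config$seed, "sampling"), {
    # each planted form appears in up to 3 spectra; the rest of the
    # budget is unmodified background peptides
    k_rep <- max(1L, min(3L, config$n_spectra %/% max(1L, nrow(gen))))
    n_bg <- max(0L, config$n_spectra - k_rep * nrow(gen))
    bg_block <- NULL
    if (n_bg > 0) {
      bg <- peps[sample(nrow(peps), n_bg, replace = TRUE), , drop = FALSE]
      mt <- modification_table()
      cam <- mt$delta_mass[mt$name == "Carbamidomethyl"]
      bg_block <- data.frame(
        chain_id = bg$chain_id, start = bg$start, end = bg$end,
        sequence = bg$sequence, mod_string = "",
        mass = vapply(bg$sequence, function(s) {
          peptide_mono_mass(s) + sum(strsplit(s, "")[[1]] == "C") * cam
        }, numeric(1)),
        label = bg$sequence, position = NA_integer_,
        state = NA_character_, stringsAsFactors = FALSE
      )
    }
    reps <- rbind(gen[rep(seq_len(nrow(gen)), k_rep), , drop = FALSE],
                  bg_block)
    reps <- reps[sample(nrow(reps)), , drop = FALSE]
    rownames(reps) <- NULL
    spectra <- simulate_spectra(reps, config)
    features <- simulate_features(chain, truth, config)
    list(chain = chain, truth = truth,
         planted_sites = planted, peptidoforms = reps,
         spectra = spectra, features = features, config = config)
  })
}

#' Search parameters matched to the synthetic study design
#'
#' The synthetic spectra are generated from peptides with at most 2
#' missed cleavages and at most 40 residues, so the companion search uses
#' the same digestion bounds (keeping the peptidoform index compact)
#' while retaining the default tolerances and modification cap.
#'
#' @param config A [sim_config()] (reserved for future condition-specific
#'   settings).
#' @return A [search_params()] object.
#' @export
sim_search_params <- function(config = sim_config()) {
  search_params(max_missed = 2, max_length = 40)
}

#' Site-level precision/recall of a catalog against planted truth
#'
#' @param catalog A `SiteCatalog` from the pipeline.
#' @param planted_sites Data.frame of planted `position`/`state` pairs
#'   (see [simulate_dataset()]).
#' @return A list with `recall`, `precision`, `n_planted`, `n_recovered`.
#' @export
evaluate_recovery <- function(catalog, planted_sites) {
  state_cols <- c(HyP = "n_HyP", HyK = "n_HyK",
                  `G-HyK` = "n_GHyK", `GG-HyK` = "n_GGHyK")
  s <- catalog$sites
  found <- vapply(seq_len(nrow(planted_sites)), function(i) {
    row <- s[s$position == planted_sites$position[i], , drop = FALSE]
    nrow(row) > 0 && row[[state_cols[[planted_sites$state[i]]]]] > 0
  }, logical(1))
  observed <- sum(vapply(seq_len(nrow(s)), function(j) {
    sum(s[j, state_cols] > 0)
  }, numeric(1)))
  list(recall = mean(found), precision = sum(found) / max(1, observed),
       n_planted = nrow(planted_sites), n_recovered = sum(found))
}
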