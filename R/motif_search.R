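#' Enumerate motif-constrained peptidoforms of a peptide
#'
#' Expands a tryptic peptide into all modification states allowed by the
#' motif rules: every proline may be unmodified or hydroxylated; every
#' lysine in the G-X-K chain context may be unmodified, hydroxylated,
#' galactosyl-hydroxylated or glucosylgalactosyl-hydroxylated; every
#' methionine may be oxidized. The motif context is taken from the full
#' chain annotation, so a peptide whose first residues lack the upstream
#' glycine still inherits the correct context. Glycosylated lysine at the
#' peptide C-terminus is disallowed unless `allow_cterm_glyco` is set
#' (bulky glycans block tryptic cleavage; plain hydroxylysine is allowed
#' anywhere). The expansion is filtered to at most `max_dynamic_mods`
#' dynamic modifications and returned in a deterministic canonical order
#' (ascending modification count, then lexicographic modification string).
#'
#' @param peptide One-row data.frame from [digest_chain()] (columns
#'   `chain_id`, `start`, `end`, `sequence`), or a list with those fields.
#' @param motifs Motif annotation of the source chain from
#'   [annotate_motifs()].
#' @param params A [search_params()] object.
#' @param mods Modification table (default [modification_table()]).
#' @return A data.frame of peptidoforms: `chain_id`, `start`, `end`,
#'   `sequence`, `mod_string` (semicolon-separated `relpos:name`, empty for
#'   the unmodified form), `n_mods`, `mass` (monoisotopic, includes static
#'   carbamidomethylation), `label` (bracketed-delta notation).
#' @export
enumerate_peptidoforms <- function(peptide, motifs,
                                   params = search_params(),
                                   mods = modification_table()) {
  seq <- peptide$sequence
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  gxk <- motifs$position[motifs$motif_class == "GXK_LYS"]
  deltas <- stats::setNames(mods$delta_mass, mods$name)

  opts <- vector("list", n) # per-position dynamic mod options (names)
  for (i in seq_len(n)) {
    r <- res[i]
    if (r == "P") {
      opts[[i]] <- "HyP"
    } else if (r == "K" && (peptide$start + i - 1L) %in% gxk) {
      o <- c("HyK", "G-HyK", "GG-HyK")
      if (i == n && !params$allow_cterm_glyco) o <- "HyK"
      opts[[i]] <- o
    } else if (r == "M") {
      opts[[i]] <- "Oxidation"
    } else {
      opts[[i]] <- character(0)
    }
  }
  space <- prod(1 + lengths(opts))
  if (space > params$enum_guard) {
    stop("peptidoform state space (", format(space, scientific = TRUE),
         ") exceeds the enumeration guard (", params$enum_guard,
         "); tighten max_length, max_missed or the modification set")
  }
  cap <- params$max_dynamic_mods
  elig <- which(lengths(opts) > 0)
  # state matrix: one row per combo, one column per eligible position;
  # 0 = unmodified, k = k-th modification option. Grown position by
  # position, pruning branches that already reached the mod cap.
  mat <- matrix(0L, nrow = 1, ncol = length(elig))
  nmods <- 0L
  for (j in seq_along(elig)) {
    k <- length(opts[[elig[j]]])
    grow <- which(nmods < cap)
    if (length(grow) > 0 && k > 0) {
      add <- mat[rep(grow, each = k), , drop = FALSE]
      add[, j] <- rep.int(seq_len(k), length(grow))
      mat <- rbind(mat, add)
      nmods <- c(nmods, nmods[grow][rep(seq_along(grow), each = k)] + 1L)
    }
  }
  static_mass <- sum(res == "C") * deltas[["Carbamidomethyl"]]
  base_mass <- peptide_mono_mass(seq) + static_mass
  # per-position delta and name lookups (index 1 = unmodified)
  total_delta <- rep(0, nrow(mat))
  strs <- matrix(NA_character_, nrow = nrow(mat), ncol = length(elig))
  for (j in seq_along(elig)) {
    od <- c(0, unname(deltas[opts[[elig[j]]]]))
    total_delta <- total_delta + od[mat[, j] + 1L]
    on <- c(NA_character_, paste0(elig[j], ":", opts[[elig[j]]]))
    strs[, j] <- on[mat[, j] + 1L]
  }
  mod_string <- if (ncol(strs) == 0) rep("", nrow(mat)) else {
    apply(strs, 1, function(x) paste(x[!is.na(x)], collapse = ";"))
  }
  out <- data.frame(chain_id = peptide$chain_id, start = peptide$start,
                    end = peptide$end, sequence = seq,
                    mod_string = mod_string, n_mods = nmods,
                    mass = base_mass + total_delta,
                    stringsAsFactors = FALSE)
  out <- out[order(out$n_mods, out$mod_string), , drop = FALSE]
  out$label <- vapply(seq_len(nrow(out)), function(i) {
    peptidoform_label(out$sequence[i], out$mod_string[i], mods)
  }, character(1))
  rownames(out) <- NULL
  out
}

#' Render a peptidoform as a bracketed-delta string
#'
#' Dialect: `"DGAAGPK[+340.1006]GDR"`, deltas to 4 decimals after the
#' modified residue.
#'
#' @param sequence Peptide sequence.
#' @param mod_string Semicolon-separated `relpos:name` string.
#' @param mods Modification table.
#' @return A single string.
#' @export
peptidoform_label <- function(sequence, mod_string,
                              mods = modification_table()) {
  if (is.na(mod_string) || !nzchar(mod_string)) return(sequence)
  deltas <- stats::setNames(mods$delta_mass, mods$name)
  parts <- strsplit(mod_string, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  pos <- vapply(kv, function(x) as.integer(x[1]), integer(1))
  nm <- vapply(kv, `[`, character(1), 2L)
  res <- strsplit(sequence, "")[[1]]
  ins <- vapply(seq_along(res), function(i) {
    j <- which(pos == i)
    if (length(j) == 0) return("")
    paste0("[", sprintf("%+.4f", sum(deltas[nm[j]])), "]")
  }, character(1))
  paste0(res, ins, collapse = "")
}

parse_mod_string <- function(mod_string) {
  if (is.na(mod_string) || !nzchar(mod_string)) {
    return(data.frame(relpos = integer(0), name = character(0)))
  }
  parts <- strsplit(mod_string, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  data.frame(relpos = vapply(kv, function(x) as.integer(x[1]), integer(1)),
             name = vapply(kv, `[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

residue_deltas <- function(sequence, mod_string, mods = modification_table()) {
  res <- strsplit(sequence, "")[[1]]
  deltas <- stats::setNames(mods$delta_mass, mods$name)
  d <- ifelse(res == "C", deltas[["Carbamidomethyl"]], 0)
  pm <- parse_mod_string(mod_string)
  if (nrow(pm)) {
    for (i in seq_len(nrow(pm))) d[pm$relpos[i]] <- d[pm$relpos[i]] + deltas[[pm$name[i]]]
  }
  d
}

#' Theoretical b/y fragment ions of a peptidoform
#'
#' Generates all b_i and y_i ions for i in 1..len-1 at charges
#' 1..`max_charge`. Modification deltas (and static
#' carbamidomethylation) are carried by every fragment containing the
#' modified residue.
#'
#' @param sequence Peptide sequence.
#' @param mod_string Dynamic modification string (`relpos:name;...`).
#' @param max_charge Highest fragment charge.
#' @param mods Modification table.
#' @return A data.frame with columns `ion` (e.g. `"b3"`, `"y5"`),
#'   `charge`, `mz`.
#' @export
theoretical_ions <- function(sequence, mod_string = "", max_charge = 2,
                             mods = modification_table()) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  if (n < 2) stop("peptide too short for fragmentation")
  m <- RESIDUE_MASS[res] + residue_deltas(sequence, mod_string, mods)
  bsum <- cumsum(m)[-n]                    # neutral b fragment residue sums
  ysum <- rev(cumsum(rev(m)))[-1]          # neutral y residue sums (y_{n-1}..y_1)
  ysum <- rev(ysum)                        # y_1 .. y_{n-1}
  out <- vector("list", max_charge)
  for (z in seq_len(max_charge)) {
    out[[z]] <- data.frame(
      ion = c(paste0("b", seq_len(n - 1)), paste0("y", seq_len(n - 1))),
      charge = z,
      mz = c((bsum + z * PROTON_MASS) / z,
             (ysum + WATER_MASS + z * PROTON_MASS) / z),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Score a peptide-spectrum match
#'
#' Transparent HCD scorer: theoretical b/y ions are matched to the nearest
#' experimental peak within the fragment tolerance (greedy by ascending
#' ppm error; each experimental peak may satisfy at most one theoretical
#' ion), and the score is the -log10 binomial tail probability of
#' observing at least that many matches by chance, with the per-ion match
#' probability estimated from the tolerance window and the spectrum's peak
#' density. Higher is better; deterministic. An empty peak list scores 0.
#'
#' @param spectrum A spectrum list with `peaks` (two-column matrix of m/z,
#'   intensity, sorted by m/z).
#' @param ions Theoretical ion table from [theoretical_ions()].
#' @param fragment_tol Fragment tolerance in ppm.
#' @return A list with `score`, `n_matched`, `n_ions`.
#' @export
score_psm <- function(spectrum, ions, fragment_tol = 20) {
  peaks <- spectrum$peaks
  n <- nrow(ions)
  if (is.null(peaks) || nrow(peaks) == 0) {
    return(list(score = 0, n_matched = 0L, n_ions = n))
  }
  pm <- peaks[, 1]
  # nearest-peak candidate for each theoretical ion
  idx <- findInterval(ions$mz, pm)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(pm))
  d_lo <- abs(pm[lo] - ions$mz)
  d_hi <- abs(pm[hi] - ions$mz)
  best <- ifelse(d_hi < d_lo, hi, lo)
  err <- abs(pm[best] - ions$mz) / ions$mz * 1e6
  ok <- which(err <= fragment_tol)
  # greedy unique assignment by ascending ppm error
  matched <- 0L
  used <- logical(length(pm))
  for (i in ok[order(err[ok])]) {
    if (!used[best[i]]) {
      used[best[i]] <- TRUE
      matched <- matched + 1L
    }
  }
  span <- max(pm) - min(pm)
  if (span <= 0) span <- 1
  width <- 2 * fragment_tol * 1e-6 * mean(ions$mz)
  p <- min(0.5, length(pm) * width / span)
  if (p <= 0) p <- .Machine$double.eps
  score <- -stats::pbinom(matched - 1L, n, p,
                          lower.tail = FALSE, log.p = TRUE) / log(10)
  list(score = score, n_matched = matched, n_ions = n)
}

#' Build a reversed-sequence decoy database
#'
#' Per-protein full sequence reversal with the id prefixed `"DECOY_"`;
#' the decoy set has the same size and residue composition as the target
#' set.
#'
#' @param chains Named list of `CollagenChain` objects.
#' @return A named list of decoy chains.
#' @export
make_decoys <- function(chains) {
  dec <- lapply(chains, function(ch) {
    rev_seq <- paste(rev(strsplit(chain_sequence(ch), "")[[1]]), collapse = "")
    collagen_chain(paste0("DECOY_", ch$id), rev_seq, species = ch$species)
  })
  names(dec) <- paste0("DECOY_", names(chains))
  dec
}

#' Build the searchable peptidoform index
#'
#' Digests target and decoy chains, enumerates motif-constrained
#' peptidoforms for every peptide within the configured length bounds, and
#' returns a single mass-sorted table. Decoy peptides whose sequence also
#' occurs in the target set are counted as target only (dropped from the
#' decoy side).
#'
#' @param chains Named list of target `CollagenChain` objects.
#' @param params A [search_params()] object.
#' @param mods Modification table.
#' @param decoys If `TRUE` (default) append reversed decoys.
#' @return A data.frame of peptidoforms with an `is_decoy` flag, sorted by
#'   mass.
#' @export
build_search_index <- function(chains, params = search_params(),
                               mods = modification_table(), decoys = TRUE) {
  all_chains <- chains
  if (decoys) all_chains <- c(chains, make_decoys(chains))
  target_ids <- vapply(chains, function(ch) ch$id, character(1))
  blocks <- vector("list", length(all_chains))
  target_seqs <- NULL
  for (k in seq_along(all_chains)) {
    ch <- all_chains[[k]]
    peps <- digest_chain(ch, max_missed = params$max_missed)
    len <- nchar(peps$sequence)
    peps <- peps[len >= params$min_length & len <= params$max_length, , drop = FALSE]
    if (nrow(peps) == 0) next
    ann <- annotate_motifs(ch)
    forms <- lapply(seq_len(nrow(peps)), function(i) {
      enumerate_peptidoforms(peps[i, ], ann, params, mods)
    })
    blk <- do.call(rbind, forms)
    blk$is_decoy <- !(ch$id %in% target_ids)
    blocks[[k]] <- blk
  }
  idx <- do.call(rbind, Filter(Negate(is.null), blocks))
  if (is.null(idx) || nrow(idx) == 0) stop("no searchable peptides in database")
  tgt_seq <- unique(idx$sequence[!idx$is_decoy])
  idx <- idx[!(idx$is_decoy & idx$sequence %in% tgt_seq), , drop = FALSE]
  idx <- idx[order(idx$mass, idx$is_decoy, idx$label), , drop = FALSE]
  rownames(idx) <- NULL
  idx
}

#' Search spectra against a peptidoform index
#'
#' For each spectrum, candidate peptidoforms within the precursor
#' tolerance are scored with [score_psm()] and the single best match is
#' retained (target-decoy competition; ties break toward target, then to
#' the lexicographically smallest peptidoform label). The search path
#' contains no randomness.
#'
#' @param spectra List of spectra (see [read_mgf()]).
#' @param index Peptidoform index from [build_search_index()], or a list
#'   of chains (the index is then built internally).
#' @param params A [search_params()] object.
#' @return A data.frame of PSMs: `spectrum_id`, `chain_id`, `start`,
#'   `end`, `sequence`, `mod_string`, `label`, `score`, `n_matched`,
#'   `is_decoy`.
#' @export
search_spectra <- function(spectra, index, params = search_params()) {
  if (!is.data.frame(index)) index <- build_search_index(index, params)
  masses <- index$mass
  out <- vector("list", length(spectra))
  for (s in seq_along(spectra)) {
    sp <- spectra[[s]]
    z <- sp$charge
    if (is.null(z) || is.na(z) || z < 1) next
    neutral <- mz_to_mass(sp$precursor_mz, z)
    tol <- params$precursor_tol * 1e-6 * neutral
    lo <- findInterval(neutral - tol, masses) + 1L
    hi <- findInterval(neutral + tol, masses)
    if (hi < lo) next
    cand <- index[lo:hi, , drop = FALSE]
    best <- NULL
    for (i in seq_len(nrow(cand))) {
      ions <- theoretical_ions(cand$sequence[i], cand$mod_string[i],
                               max_charge = min(params$max_fragment_charge,
                                                max(1L, z - 1L)))
      sc <- score_psm(sp, ions, params$fragment_tol)
      rec <- list(score = sc$score, n_matched = sc$n_matched, i = i)
      better <- is.null(best) || rec$score > best$score
      if (!better && !is.null(best) && rec$score == best$score) {
        if (cand$is_decoy[best$i] && !cand$is_decoy[i]) {
          better <- TRUE
        } else if (cand$is_decoy[i] == cand$is_decoy[best$i] &&
                   cand$label[i] < cand$label[best$i]) {
          better <- TRUE
        }
      }
      if (better) best <- rec
    }
    if (is.null(best)) next
    b <- cand[best$i, , drop = FALSE]
    out[[s]] <- data.frame(
      spectrum_id = sp$id, chain_id = b$chain_id, start = b$start,
      end = b$end, sequence = b$sequence, mod_string = b$mod_string,
      label = b$label, score = best$score, n_matched = best$n_matched,
      is_decoy = b$is_decoy, stringsAsFactors = FALSE
    )
  }
  psms <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(psms)) {
    psms <- data.frame(spectrum_id = character(0), chain_id = character(0),
                       start = integer(0), end = integer(0),
                       sequence = character(0), mod_string = character(0),
                       label = character(0), score = numeric(0),
                       n_matched = integer(0), is_decoy = logical(0))
  }
  rownames(psms) <- NULL
  psms
}

#' Target-decoy q-values and FDR filtering
#'
#' Estimates, for each score cutoff, the false discovery rate as
#' `#decoys >= cutoff / #targets >= cutoff`, converts it to a q-value
#' (minimum FDR over all cutoffs at or below the PSM's score, hence
#' monotone non-increasing in score) and retains PSMs with
#' `q <= threshold`. With `level = "peptide"` or `"protein"` the
#' competition is repeated on each unit's best PSM score.
#'
#' @param psms PSM table from [search_spectra()] (one best PSM per
#'   spectrum).
#' @param threshold q-value threshold (default 0.01).
#' @param level `"psm"`, `"peptide"` or `"protein"`.
#' @param keep_decoys Keep passing decoys in the output (default FALSE).
#' @return The filtered PSM table with a `q_value` column.
#' @export
fdr_filter <- function(psms, threshold = 0.01,
                       level = c("psm", "peptide", "protein"),
                       keep_decoys = FALSE) {
  level <- match.arg(level)
  if (nrow(psms) == 0) {
    psms$q_value <- numeric(0)
    return(psms)
  }
  if (sum(!psms$is_decoy) == 0) stop("no target PSMs; cannot estimate FDR")
  unit <- switch(level,
    psm = seq_len(nrow(psms)),
    peptide = match(psms$label, unique(psms$label)),
    protein = match(psms$chain_id, unique(psms$chain_id))
  )
  if (level != "psm") {
    # keep each unit's best-scoring PSM
    o1 <- order(psms$score, decreasing = TRUE)
    psms <- psms[o1, , drop = FALSE]
    psms <- psms[!duplicated(unit[o1]), , drop = FALSE]
  }
  o <- order(psms$score, decreasing = TRUE)
  dec <- cumsum(psms$is_decoy[o])
  tgt <- cumsum(!psms$is_decoy[o])
  fdr <- dec / pmax(tgt, 1)
  q <- rev(cummin(rev(fdr)))
  psms$q_value[o] <- q
  res <- psms[psms$q_value <= threshold, , drop = FALSE]
  if (!keep_decoys) res <- res[!res$is_decoy, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write a PSM table as TSV
#' @param psms PSM table.
#' @param path Output path.
#' @param comment Optional header comment line(s), written prefixed `#`.
#' @return `path`, invisibly.
#' @export
write_psms <- function(psms, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(psms, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
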