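#' The collagen PTM modification table
#'
#' Returns the variable and static modifications used by the
#' motif-constrained search, with monoisotopic delta masses derived at run
#' time from elemental composition: hydroxylation adds one oxygen;
#' galactosyl-hydroxylysine adds one oxygen plus one hexose (C6H10O5);
#' glucosylgalactosyl-hydroxylysine adds one oxygen plus two hexoses.
#' Hydroxylysine and its glycoforms are restricted to lysines in the G-X-K
#' motif context; hydroxyproline and methionine oxidation are
#' unconstrained; carbamidomethylation of cysteine is static. The `printed`
#' column keeps the delta-mass strings commonly quoted for these
#' modifications (the quoted hydroxylysine value, +15.994916, differs from
#' the oxygen monoisotopic mass by 1 micro-Dalton; internally all
#' single-oxygen deltas share the oxygen mass).
#'
#' @return A data.frame with columns `name`, `target` (residue letter or
#'   `"peptide-nterm"`), `motif` (`GXK_LYS` or `NA`), `delta_mass` (Da),
#'   `mode` (`static`/`dynamic`), `printed`.
#' @examples
#' modification_table()
#' @export
modification_table <- function() {
  O <- ELEMENT_MASS[["O"]]
  hexose <- 6 * ELEMENT_MASS[["C"]] + 10 * ELEMENT_MASS[["H"]] +
    5 * ELEMENT_MASS[["O"]]
  acetyl <- 2 * ELEMENT_MASS[["C"]] + 2 * ELEMENT_MASS[["H"]] +
    ELEMENT_MASS[["O"]]
  cam <- 2 * ELEMENT_MASS[["C"]] + 3 * ELEMENT_MASS[["H"]] +
    ELEMENT_MASS[["N"]] + ELEMENT_MASS[["O"]]
  data.frame(
    name = c("HyP", "HyK", "G-HyK", "GG-HyK",
             "Carbamidomethyl", "Oxidation", "Acetyl"),
    target = c("P", "K", "K", "K", "C", "M", "peptide-nterm"),
    motif = c(NA, "GXK_LYS", "GXK_LYS", "GXK_LYS", NA, NA, NA),
    delta_mass = c(O, O, O + hexose, O + 2 * hexose, cam, O, acetyl),
    mode = c("dynamic", "dynamic", "dynamic", "dynamic",
             "static", "dynamic", "dynamic"),
    printed = c("+15.9949", "+15.994916", "+178.047738", "+340.100562",
                "+57.0236", "+15.9949", "+42.010565"),
    stringsAsFactors = FALSE
  )
}

#' Write the modification table as TSV
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_modification_table <- function(path) {
  utils::write.table(modification_table(), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' In-silico fully tryptic digestion
#'
#' Cleaves after lysine or arginine except when the next residue is
#' proline, and emits every fully tryptic peptide with 0 to `max_missed`
#' internal missed cleavage sites. Peptide bounds are reported in
#' full-length chain coordinates. No length filter is applied here (so the
#' 0-missed-cleavage peptides partition the chain); search candidacy
#' filtering happens in [search_params()].
#'
#' @param chain A `CollagenChain`.
#' @param max_missed Maximum internal missed cleavages (default 4).
#' @return A data.frame with columns `chain_id`, `start`, `end`,
#'   `sequence`, `missed_cleavages`.
#' @export
digest_chain <- function(chain, max_missed = 4) {
  stopifnot(inherits(chain, "CollagenChain"))
  seq <- chain_sequence(chain)
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  # cut points: cleavage occurs after position i
  cuts <- which(res %in% c("K", "R"))
  cuts <- cuts[cuts < n & res[cuts + 1L] != "P" | cuts == n]
  # segment boundaries: peptides run between consecutive cut points
  bounds <- c(0L, cuts[cuts < n], n)
  bounds <- unique(bounds)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  m <- length(starts)
  out <- vector("list", m)
  for (i in seq_len(m)) {
    jmax <- min(m, i + max_missed)
    js <- i:jmax
    out[[i]] <- data.frame(
      chain_id = chain$id,
      start = starts[i],
      end = ends[js],
      sequence = substring(seq, starts[i], ends[js]),
      missed_cleavages = js - i,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water, plus any
#' modification delta masses. Mass is additive in the deltas and
#' independent of their order.
#'
#' @param sequence Peptide sequence (standard residues).
#' @param mod_deltas Numeric vector of modification delta masses (Da).
#' @return Monoisotopic mass in Da.
#' @examples
#' peptide_mono_mass("G") # 75.032...
#' @export
peptide_mono_mass <- function(sequence, mod_deltas = numeric(0)) {
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(res), AA_ALPHABET)
  if (length(bad) > 0) stop("unknown residue(s): ", paste(bad, collapse = ", "))
  sum(RESIDUE_MASS[res]) + WATER_MASS + sum(mod_deltas)
}

#' Neutral mass to m/z
#' @param mass Neutral monoisotopic mass (Da).
#' @param charge Positive integer charge.
#' @return m/z of the protonated species.
#' @export
mass_to_mz <- function(mass, charge) {
  if (any(charge < 1)) stop("charge must be >= 1")
  (mass + charge * PROTON_MASS) / charge
}

#' m/z to neutral mass
#' @param mz Observed m/z.
#' @param charge Positive integer charge.
#' @return Neutral mass (Da).
#' @export
mz_to_mass <- function(mz, charge) {
  if (any(charge < 1)) stop("charge must be >= 1")
  mz * charge - charge * PROTON_MASS
}

#' Relative mass error in parts per million
#'
#' Convention: `(observed - theoretical) / theoretical * 1e6`.
#' @param observed,theoretical Masses or m/z values.
#' @return Signed ppm error.
#' @export
ppm_error <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}

#' Search parameter set
#'
#' Bundles the tolerances and combinatorial limits of the
#' motif-constrained search. Two presets mirror common engine
#' parameterizations: `"subset"` (default; precursor 10 ppm, fragment
#' 20 ppm, 4 missed cleavages, up to 10 dynamic modifications) and
#' `"wide"` (50/25 ppm, 3 missed cleavages, up to 5 dynamic
#' modifications).
#'
#' @param preset `"subset"` or `"wide"`; explicit arguments override.
#' @param precursor_tol Precursor tolerance, ppm.
#' @param fragment_tol Fragment tolerance, ppm.
#' @param max_missed Maximum missed cleavages.
#' @param max_dynamic_mods Cap on dynamic modifications per peptidoform.
#' @param fdr_threshold PSM q-value threshold, in (0,1).
#' @param min_length,max_length Peptide length bounds for search candidacy.
#' @param max_fragment_charge Highest fragment charge generated.
#' @param enum_guard Error if a peptide's uncapped peptidoform state space
#'   exceeds this bound.
#' @param allow_cterm_glyco Allow glycosylated lysine at the peptide
#'   C-terminus (default FALSE: a bulky glycan blocks tryptic cleavage;
#'   plain hydroxylysine is allowed anywhere).
#' @return A list of class `search_params`.
#' @export
search_params <- function(preset = c("subset", "wide"),
                          precursor_tol = NULL, fragment_tol = NULL,
                          max_missed = NULL, max_dynamic_mods = NULL,
                          fdr_threshold = 0.01,
                          min_length = 5, max_length = 60,
                          max_fragment_charge = 2,
                          enum_guard = 1e6,
                          allow_cterm_glyco = FALSE) {
  preset <- match.arg(preset)
  def <- switch(preset,
    subset = list(precursor_tol = 10, fragment_tol = 20,
                  max_missed = 4, max_dynamic_mods = 10),
    wide = list(precursor_tol = 50, fragment_tol = 25,
                max_missed = 3, max_dynamic_mods = 5)
  )
  p <- list(
    preset = preset,
    precursor_tol = precursor_tol %||% def$precursor_tol,
    fragment_tol = fragment_tol %||% def$fragment_tol,
    max_missed = max_missed %||% def$max_missed,
    max_dynamic_mods = max_dynamic_mods %||% def$max_dynamic_mods,
    fdr_threshold = fdr_threshold,
    min_length = min_length, max_length = max_length,
    max_fragment_charge = max_fragment_charge,
    enum_guard = enum_guard,
    allow_cterm_glyco = allow_cterm_glyco
  )
  if (p$precursor_tol <= 0 || p$fragment_tol <= 0) stop("tolerances must be > 0")
  if (p$fdr_threshold <= 0 || p$fdr_threshold >= 1) {
    stop("fdr_threshold must be in (0,1)")
  }
  structure(p, class = "search_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
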