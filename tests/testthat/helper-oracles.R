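# Independent oracles used across the suite. These deliberately share no
# code with the package: brute-force scans, exhaustive enumeration and
# elemental-composition arithmetic.

# ---- elemental-composition peptide mass ------------------------------------
# residue formulas (peptide-bond residues) and independently sourced
# monoisotopic element masses
oracle_elements <- c(H = 1.0078250319, C = 12.0, N = 14.0030740052,
                     O = 15.9949146221, S = 31.97207069)
oracle_formulas <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

oracle_formula_mass <- function(formula) {
  sum(oracle_elements[names(formula)] * formula)
}

oracle_peptide_mass <- function(sequence, extra_formulas = list()) {
  res <- strsplit(sequence, "")[[1]]
  m <- sum(vapply(res, function(r) oracle_formula_mass(oracle_formulas[[r]]),
                  numeric(1)))
  m <- m + oracle_formula_mass(c(H = 2, O = 1)) # water
  for (f in extra_formulas) m <- m + oracle_formula_mass(f)
  m
}

# ---- brute-force motif window scan -----------------------------------------
oracle_motifs <- function(sequence) {
  res <- strsplit(sequence, "")[[1]]
  out <- list()
  for (p in seq_along(res)) {
    r <- res[p]
    if (!r %in% c("P", "K")) next
    cls <- "NONE"
    if (r == "P") {
      if (p >= 3 && res[p - 2] == "G") cls <- "YAA_PRO"
      else if (p >= 2 && res[p - 1] == "G") cls <- "XAA_PRO"
    } else {
      if (p >= 3 && res[p - 2] == "G") cls <- "GXK_LYS"
    }
    out[[length(out) + 1L]] <- data.frame(position = p, residue = r,
                                          motif_class = cls)
  }
  do.call(rbind, out)
}

# ---- brute-force tryptic digestion (all-substrings filter) -----------------
oracle_digest <- function(sequence, max_missed) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  is_site <- function(i) {
    i >= 1 && i < n && res[i] %in% c("K", "R") && res[i + 1] != "P"
  }
  out <- list()
  for (s in 1:n) for (e in s:n) {
    if (!(s == 1 || is_site(s - 1))) next
    if (!(e == n || is_site(e))) next
    internal <- if (e > s) sum(vapply(s:(e - 1), is_site, logical(1))) else 0
    if (internal > max_missed) next
    out[[length(out) + 1L]] <- data.frame(
      start = s, end = e, sequence = substr(sequence, s, e),
      missed_cleavages = internal
    )
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$end), ]
}

# ---- brute-force peptidoform count -----------------------------------------
# counts assignments over per-position state-option lists with at most
# `cap` modified positions, via full Cartesian expansion
oracle_form_count <- function(n_options, cap) {
  if (length(n_options) == 0) return(1L)
  grids <- lapply(n_options, function(k) 0:k)
  g <- do.call(expand.grid, grids)
  sum(rowSums(g > 0) <= cap)
}

# ---- exhaustive global alignment enumeration -------------------------------
# enumerates every global alignment path and scores it with BLOSUM62 and
# affine gaps (gap run of length L costs open + extend * L)
oracle_align_score <- function(q, r, open = 10, extend = 0.5) {
  if (!exists("BLOSUM62", inherits = TRUE)) {
    utils::data("BLOSUM62", package = "Biostrings", envir = globalenv())
  }
  sub <- get("BLOSUM62", envir = globalenv())
  qr <- strsplit(q, "")[[1]]
  rr <- strsplit(r, "")[[1]]
  best <- -Inf
  score_path <- function(qa, ra) {
    s <- 0
    run <- 0 # current gap run length (either side)
    for (k in seq_along(qa)) {
      if (qa[k] == "-" || ra[k] == "-") {
        run <- run + 1
      } else {
        if (run > 0) {
          s <- s - open - extend * run
          run <- 0
        }
        s <- s + sub[qa[k], ra[k]]
      }
    }
    if (run > 0) s <- s - open - extend * run
    s
  }
  recurse <- function(i, j, qa, ra) {
    if (i > length(qr) && j > length(rr)) {
      sc <- score_path(qa, ra)
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (i <= length(qr) && j <= length(rr)) {
      recurse(i + 1, j + 1, c(qa, qr[i]), c(ra, rr[j]))
    }
    if (i <= length(qr)) recurse(i + 1, j, c(qa, qr[i]), c(ra, "-"))
    if (j <= length(rr)) recurse(i, j + 1, c(qa, "-"), c(ra, rr[j]))
  }
  recurse(1, 1, character(0), character(0))
  best
}

# ---- one-way ANOVA sums-of-squares decomposition ---------------------------
oracle_anova_F <- function(values, groups) {
  groups <- as.factor(groups)
  grand <- mean(values)
  k <- nlevels(groups)
  n <- length(values)
  ss_between <- sum(tapply(values, groups, function(x) {
    length(x) * (mean(x) - grand)^2
  }))
  ss_within <- sum(unlist(lapply(split(values, groups), function(x) {
    (x - mean(x))^2
  })))
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

# ---- small chain builders --------------------------------------------------
make_test_chain <- function(id = "testchain",
                            seq = "MKWVTFAAGPPGPKGDRGAPGPAGPPGPKGDTGRAAK") {
  collagen_chain(id, seq)
}

random_chain_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("G", "P", "K", "R", "A", "S", "E", "D", "L", "V"), n,
               replace = TRUE, prob = c(.25, .2, .08, .07, .12, .08, .06,
                                        .05, .05, .04)), collapse = "")
}
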