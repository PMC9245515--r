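#' Construct a collagen chain
#'
#' A `CollagenChain` holds a protein sequence in full-length, 1-based
#' coordinates (including the signal peptide, matching the convention used
#' for site labels such as K1017), together with optional annotations for
#' the signal peptide and the N- and C-terminal propeptides. The "mature"
#' chain is the helical region left after removal of those segments and is
#' exposed as a coordinate view, not stored.
#'
#' @param id Chain identifier (e.g. `"COL1A1a"`).
#' @param sequence Amino-acid sequence using the 20 standard one-letter
#'   codes. Lowercase input is uppercased.
#' @param species Optional species tag.
#' @param signal_peptide,n_propeptide,c_propeptide Closed position intervals
#'   given as length-2 integer vectors `c(start, end)`, or `NULL` if unknown.
#'   Intervals must be disjoint, ordered signal < N-propeptide < helical
#'   core < C-propeptide, and lie within the sequence.
#' @return An object of class `CollagenChain`.
#' @examples
#' ch <- collagen_chain("colX", "GPPGPKGDRGAPGPA")
#' nchar(chain_sequence(ch))
#' @export
collagen_chain <- function(id, sequence, species = NA_character_,
                           signal_peptide = NULL, n_propeptide = NULL,
                           c_propeptide = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || !nzchar(sequence)) {
    stop("chain '", id, "': sequence must be a non-empty string")
  }
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), AA_ALPHABET)
  if (length(bad) > 0) {
    stop("chain '", id, "': sequence contains non-standard residue letter(s): ",
         paste(bad, collapse = ", "))
  }
  chain <- structure(
    list(id = id, species = species, sequence = sequence,
         signal_peptide = NULL, n_propeptide = NULL, c_propeptide = NULL),
    class = "CollagenChain"
  )
  set_chain_intervals(chain, signal_peptide = signal_peptide,
                      n_propeptide = n_propeptide, c_propeptide = c_propeptide)
}

check_interval <- function(x, label, n) {
  if (is.null(x)) return(NULL)
  x <- as.integer(x)
  if (length(x) != 2L || anyNA(x) || x[1] > x[2] || x[1] < 1L || x[2] > n) {
    stop(label, " interval must be c(start, end) within [1, ", n, "]")
  }
  x
}

#' Set or replace segment annotations on a chain
#'
#' @param chain A `CollagenChain`.
#' @inheritParams collagen_chain
#' @return The chain with validated intervals set.
#' @export
set_chain_intervals <- function(chain, signal_peptide = NULL,
                                n_propeptide = NULL, c_propeptide = NULL) {
  stopifnot(inherits(chain, "CollagenChain"))
  n <- nchar(chain$sequence)
  sp <- check_interval(signal_peptide, "signal_peptide", n)
  np <- check_interval(n_propeptide, "n_propeptide", n)
  cp <- check_interval(c_propeptide, "c_propeptide", n)
  ivs <- Filter(Negate(is.null), list(sp, np, cp))
  if (length(ivs) > 1) {
    o <- order(vapply(ivs, `[`, integer(1), 1L))
    ivs <- ivs[o]
    for (i in seq_len(length(ivs) - 1L)) {
      if (ivs[[i]][2] >= ivs[[i + 1L]][1]) {
        stop("chain segments must be disjoint and ordered")
      }
    }
  }
  # enforce biological ordering: signal < N-pro < C-pro
  ends <- c(if (!is.null(sp)) sp[2] else -Inf,
            if (!is.null(np)) np[2] else NA,
            if (!is.null(cp)) cp[1] else NA)
  if (!is.null(sp) && !is.null(np) && sp[2] >= np[1]) {
    stop("signal peptide must precede the N-propeptide")
  }
  if (!is.null(np) && !is.null(cp) && np[2] >= cp[1]) {
    stop("N-propeptide must precede the C-propeptide")
  }
  if (!is.null(sp) && !is.null(cp) && sp[2] >= cp[1]) {
    stop("signal peptide must precede the C-propeptide")
  }
  chain$signal_peptide <- sp
  chain$n_propeptide <- np
  chain$c_propeptide <- cp
  chain
}

#' @export
print.CollagenChain <- function(x, ...) {
  fmt_iv <- function(iv) if (is.null(iv)) "absent" else paste0(iv[1], "-", iv[2])
  cat("CollagenChain '", x$id, "' (", nchar(x$sequence), " aa",
      if (!is.na(x$species)) paste0(", ", x$species), ")\n", sep = "")
  cat("  signal peptide: ", fmt_iv(x$signal_peptide),
      "  N-propeptide: ", fmt_iv(x$n_propeptide),
      "  C-propeptide: ", fmt_iv(x$c_propeptide), "\n", sep = "")
  invisible(x)
}

#' Chain sequence accessor
#' @param chain A `CollagenChain`.
#' @return The amino-acid sequence as a single string.
#' @export
chain_sequence <- function(chain) {
  stopifnot(inherits(chain, "CollagenChain"))
  chain$sequence
}

#' Read collagen chains from a FASTA file
#'
#' Each record becomes one [collagen_chain()] with the id taken from the
#' first whitespace-delimited token of the header. Segment annotations are
#' absent until set (see [transfer_cleavage_sites()] or
#' [read_cleavage_config()]).
#'
#' @param path Path to a FASTA file.
#' @param species Optional species tag applied to every chain.
#' @return A named list of `CollagenChain` objects.
#' @export
read_collagen_fasta <- function(path, species = NA_character_) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) stop("empty FASTA input: ", path)
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA: line ", first, " does not start a '>' header")
  }
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) stop("empty FASTA input: ", path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  chains <- lapply(seq_along(seqs), function(i) {
    collagen_chain(ids[i], as.character(seqs[[i]]), species = species)
  })
  names(chains) <- ids
  chains
}

#' Write chains to a FASTA file
#' @param chains List of `CollagenChain` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_collagen_fasta <- function(chains, path) {
  seqs <- Biostrings::AAStringSet(vapply(chains, chain_sequence, character(1)))
  names(seqs) <- vapply(chains, function(ch) ch$id, character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Annotate Gly-Xaa-Yaa and G-X-K motif context
#'
#' Classifies every proline and lysine of the chain by its position in the
#' collagen triple-helical repeat: a proline preceded by glycine two
#' residues upstream sits in the Yaa position (`YAA_PRO`, 4-hydroxylation
#' eligible), a proline directly preceded by glycine sits in the Xaa
#' position (`XAA_PRO`, 3-hydroxylation eligible), and a lysine preceded by
#' glycine two residues upstream is in the G-X-K context (`GXK_LYS`,
#' hydroxylation/O-glycosylation eligible). A proline that qualifies for
#' both roles in overlapping frames (e.g. the middle of "GPPG P")
#' is classified `YAA_PRO`, since Yaa 4-hydroxylation is the dominant,
#' near-complete modification; its Xaa-frame context is still visible in
#' `triplet_context`. All other positions are `NONE`.
#'
#' @param chain A `CollagenChain`.
#' @return A data.frame with columns `position`, `residue`, `motif_class`,
#'   `triplet_context` covering every P and K of the chain.
#' @export
annotate_motifs <- function(chain) {
  stopifnot(inherits(chain, "CollagenChain"))
  seq <- chain_sequence(chain)
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  pos <- which(res %in% c("P", "K"))
  if (length(pos) == 0) {
    return(data.frame(position = integer(0), residue = character(0),
                      motif_class = character(0), triplet_context = character(0),
                      stringsAsFactors = FALSE))
  }
  cls <- character(length(pos))
  ctx <- rep(NA_character_, length(pos))
  for (i in seq_along(pos)) {
    p <- pos[i]
    r <- res[p]
    g2 <- p >= 3 && res[p - 2] == "G"   # residue is in the Yaa slot
    g1 <- p >= 2 && res[p - 1] == "G"   # residue is in the Xaa slot
    if (r == "P") {
      if (g2) {
        cls[i] <- "YAA_PRO"
        ctx[i] <- substr(seq, p - 2, p)
      } else if (g1) {
        cls[i] <- "XAA_PRO"
        ctx[i] <- substr(seq, p - 1, min(p + 1, n))
      } else {
        cls[i] <- "NONE"
      }
    } else { # K
      if (g2) {
        cls[i] <- "GXK_LYS"
        ctx[i] <- substr(seq, p - 2, p)
      } else {
        cls[i] <- "NONE"
      }
    }
  }
  data.frame(position = pos, residue = res[pos], motif_class = cls,
             triplet_context = ctx, stringsAsFactors = FALSE)
}

#' Write per-residue motif annotation as TSV
#' @param chains List of `CollagenChain` objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_chain_annotation <- function(chains, path) {
  rows <- lapply(chains, function(ch) {
    ann <- annotate_motifs(ch)
    if (nrow(ann) == 0) return(NULL)
    cbind(chain_id = ch$id, ann)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Global pairwise alignment between two chains
#'
#' Needleman-Wunsch global alignment with a BLOSUM62 substitution matrix
#' and affine gap penalties (a gap of length L costs
#' `gap_open + gap_extend * L`). Used to transfer propeptide cleavage sites
#' from an annotated ortholog and to map conserved PTM sites across
#' species.
#'
#' @param query,reference Sequences as strings or `CollagenChain` objects.
#' @param substitution_matrix Name of a matrix bundled with Biostrings
#'   (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return An object of class `ChainAlignment`: a list with `pairs` (a
#'   data.frame of aligned `qpos`/`rpos` index pairs with a `match` flag;
#'   strictly increasing on both sides; gapped positions are absent),
#'   `score`, and the gapped `query_aln`/`reference_aln` strings.
#' @export
align_global <- function(query, reference, substitution_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  as_seq <- function(x) if (inherits(x, "CollagenChain")) chain_sequence(x) else toupper(as.character(x))
  q <- as_seq(query)
  r <- as_seq(reference)
  if (!nzchar(q) || !nzchar(r)) stop("alignment requires non-empty sequences")
  mat <- get(data(list = substitution_matrix,
                  package = "Biostrings",
                  envir = environment()))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(r),
    substitutionMatrix = mat, type = "global",
    gapOpening = gap_open, gapExtension = gap_extend
  )
  qa <- as.character(Biostrings::alignedPattern(aln))
  ra <- as.character(Biostrings::alignedSubject(aln))
  qres <- strsplit(qa, "")[[1]]
  rres <- strsplit(ra, "")[[1]]
  qpos <- cumsum(qres != "-")
  rpos <- cumsum(rres != "-")
  keep <- qres != "-" & rres != "-"
  pairs <- data.frame(qpos = qpos[keep], rpos = rpos[keep],
                      match = qres[keep] == rres[keep])
  structure(list(pairs = pairs, score = Biostrings::score(aln),
                 query_aln = qa, reference_aln = ra,
                 params = list(substitution_matrix = substitution_matrix,
                               gap_open = gap_open, gap_extend = gap_extend)),
            class = "ChainAlignment")
}

#' @export
print.ChainAlignment <- function(x, ...) {
  cat("ChainAlignment: ", nrow(x$pairs), " aligned pairs, score ",
      format(x$score), "\n", sep = "")
  invisible(x)
}

#' Map a reference position through an alignment
#'
#' @param alignment A `ChainAlignment` from [align_global()].
#' @param rpos Reference position(s).
#' @param snap Snap window: if `rpos` falls in a gap, the nearest aligned
#'   reference position within `snap` residues is used (ties break toward
#'   the upstream side). `snap = 0` disables snapping.
#' @return Query positions; `NA` where unmappable within the window.
#' @export
map_position <- function(alignment, rpos, snap = 0) {
  stopifnot(inherits(alignment, "ChainAlignment"))
  pr <- alignment$pairs
  vapply(rpos, function(b) {
    hit <- match(b, pr$rpos)
    if (!is.na(hit)) return(pr$qpos[hit])
    if (snap > 0) {
      for (d in seq_len(snap)) {
        for (cand in c(b - d, b + d)) {
          hit <- match(cand, pr$rpos)
          if (!is.na(hit)) return(pr$qpos[hit])
        }
      }
    }
    NA_integer_
  }, integer(1))
}

#' Transfer propeptide cleavage sites from an annotated ortholog
#'
#' Maps the segment boundaries (signal peptide, N- and C-terminal
#' propeptides) of an annotated reference chain onto the query chain
#' through a global alignment. Boundaries that fall opposite an alignment
#' gap snap to the nearest aligned reference residue within `snap`
#' positions; beyond that the transfer fails loudly rather than guess.
#' The outermost boundaries (start of the first segment, end of the last)
#' are pinned to the chain termini, as propeptide/signal segments are
#' terminal by construction.
#'
#' @param chain Query `CollagenChain` (annotations will be set).
#' @param reference Reference `CollagenChain` with intervals set.
#' @param alignment Optional precomputed `ChainAlignment` of
#'   `chain` (query) vs `reference`; computed with defaults if omitted.
#' @param snap Snap window in aligned residues (default 3).
#' @return `chain` with signal/propeptide intervals set.
#' @export
transfer_cleavage_sites <- function(chain, reference, alignment = NULL, snap = 3) {
  stopifnot(inherits(chain, "CollagenChain"), inherits(reference, "CollagenChain"))
  segs <- list(signal_peptide = reference$signal_peptide,
               n_propeptide = reference$n_propeptide,
               c_propeptide = reference$c_propeptide)
  if (all(vapply(segs, is.null, logical(1)))) {
    stop("reference chain '", reference$id, "' has no segment annotations to transfer")
  }
  if (is.null(alignment)) alignment <- align_global(chain, reference)
  n <- nchar(chain_sequence(chain))
  mapped <- lapply(names(segs), function(nm) {
    iv <- segs[[nm]]
    if (is.null(iv)) return(NULL)
    q <- map_position(alignment, iv, snap = snap)
    if (anyNA(q)) {
      bad <- iv[is.na(q)]
      stop("cannot map ", nm, " boundary position(s) ",
           paste(bad, collapse = ", "), " of reference '", reference$id,
           "' within a ", snap, "-residue snap window")
    }
    q
  })
  names(mapped) <- names(segs)
  # terminal segments are pinned to the chain ends
  if (!is.null(mapped$signal_peptide)) {
    if (segs$signal_peptide[1] == 1L) mapped$signal_peptide[1] <- 1L
  } else if (!is.null(mapped$n_propeptide) && segs$n_propeptide[1] == 1L) {
    mapped$n_propeptide[1] <- 1L
  }
  rn <- nchar(chain_sequence(reference))
  if (!is.null(mapped$c_propeptide) && segs$c_propeptide[2] == rn) {
    mapped$c_propeptide[2] <- n
  }
  set_chain_intervals(chain,
                      signal_peptide = mapped$signal_peptide,
                      n_propeptide = mapped$n_propeptide,
                      c_propeptide = mapped$c_propeptide)
}

#' Mature (processed-chain) coordinate range
#'
#' The mature chain runs from the first residue after the signal peptide /
#' N-propeptide to the last residue before the C-propeptide.
#'
#' @param chain A `CollagenChain`.
#' @return Integer `c(start, end)` in full-length coordinates.
#' @export
mature_range <- function(chain) {
  stopifnot(inherits(chain, "CollagenChain"))
  n <- nchar(chain_sequence(chain))
  start <- 1L
  if (!is.null(chain$signal_peptide)) start <- max(start, chain$signal_peptide[2] + 1L)
  if (!is.null(chain$n_propeptide)) start <- max(start, chain$n_propeptide[2] + 1L)
  end <- if (!is.null(chain$c_propeptide)) chain$c_propeptide[1] - 1L else n
  if (start > end) stop("chain '", chain$id, "' has an empty mature range")
  c(start, end)
}

#' Convert a full-length position to mature numbering
#' @param chain A `CollagenChain` with segment annotations.
#' @param position Full-length position(s).
#' @return Mature position(s) (1 = first residue after the N-propeptide).
#' @export
to_mature <- function(chain, position) {
  mr <- mature_range(chain)
  if (any(position < mr[1] | position > mr[2])) {
    stop("position(s) ", paste(position[position < mr[1] | position > mr[2]],
                               collapse = ", "),
         " not in mature chain (", mr[1], "-", mr[2], ")")
  }
  as.integer(position - mr[1] + 1L)
}

#' Convert a mature position to full-length numbering
#' @inheritParams to_mature
#' @param position Mature position(s).
#' @export
to_full <- function(chain, position) {
  mr <- mature_range(chain)
  full <- as.integer(position + mr[1] - 1L)
  if (any(full < mr[1] | full > mr[2])) {
    stop("mature position(s) out of range 1-", mr[2] - mr[1] + 1L)
  }
  full
}

#' Read segment annotations from a plain-text config
#'
#' The config is a TSV with columns `chain_id`, `segment` (one of
#' `signal_peptide`, `n_propeptide`, `c_propeptide`), `start`, `end`.
#'
#' @param chains Named list of `CollagenChain` objects.
#' @param path TSV path.
#' @return The list of chains with intervals applied.
#' @export
read_cleavage_config <- function(chains, path) {
  cfg <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("chain_id", "segment", "start", "end")
  if (!all(need %in% names(cfg))) {
    stop("cleavage config must have columns: ", paste(need, collapse = ", "))
  }
  for (id in unique(cfg$chain_id)) {
    if (!id %in% names(chains)) next
    sub <- cfg[cfg$chain_id == id, ]
    args <- list(chain = chains[[id]])
    for (i in seq_len(nrow(sub))) {
      seg <- sub$segment[i]
      if (!seg %in% c("signal_peptide", "n_propeptide", "c_propeptide")) {
        stop("unknown segment '", seg, "' in cleavage config")
      }
      args[[seg]] <- c(sub$start[i], sub$end[i])
    }
    chains[[id]] <- do.call(set_chain_intervals, args)
  }
  chains
}
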