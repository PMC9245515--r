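#' Collapse filtered PSMs into a site-specific PTM catalog
#'
#' Accumulates per-position modification states over all passing target
#' PSMs and applies the positional hydroxyproline assignment rule:
#' a hydroxylated proline in the Yaa slot of the Gly-Xaa-Yaa repeat is
#' 4-hydroxyproline (`HYP4`); a hydroxylated proline in the Xaa slot is
#' 3-hydroxyproline (`HYP3`) only when the Yaa residue of its triplet is a
#' proline observed hydroxylated on the same peptidoform (the G-Xaa-HyP
#' rule); an Xaa hydroxyproline whose Yaa partner is not a hydroxylated
#' proline (or a hydroxyproline with no glycine context at all) is
#' `HYP_AMBIGUOUS`. Lysine sites (always in the G-X-K context, enforced at
#' enumeration) are `LYS_SITE` and carry their observed state set
#' (hydroxylysine and the two glycoforms, plus unmodified support).
#'
#' @param psms FDR-filtered target PSM table (see [fdr_filter()]); decoy
#'   rows are rejected.
#' @param chains Named list of `CollagenChain` objects; every PSM
#'   `chain_id` must resolve.
#' @param relaxed_hyp3 If `TRUE`, the Yaa-hydroxylation co-occurrence
#'   requirement is relaxed to "observed at that position in any
#'   peptidoform".
#' @param min_psms Minimum per-state PSM support for a state to be
#'   recorded (default 1).
#' @return An object of class `SiteCatalog`: a list with `sites` (one row
#'   per modified chain position with state counts and classification) and
#'   `coverage` (per-chain percent of the mature chain covered by
#'   identified peptides; `NA` when the mature range is not annotated).
#' @export
assign_sites <- function(psms, chains, relaxed_hyp3 = FALSE, min_psms = 1) {
  if (any(psms$is_decoy)) stop("decoy PSMs must be removed before cataloging")
  unknown <- setdiff(unique(psms$chain_id), names(chains))
  if (length(unknown) > 0) {
    stop("PSM(s) reference unknown chain(s): ", paste(unknown, collapse = ", "))
  }
  empty_sites <- data.frame(
    chain_id = character(0), position = integer(0),
    position_mature = integer(0), residue = character(0),
    motif_class = character(0), classification = character(0),
    states = character(0), n_unmod = integer(0), n_HyP = integer(0),
    n_HyK = integer(0), n_GHyK = integer(0), n_GGHyK = integer(0),
    stringsAsFactors = FALSE
  )
  cov <- catalog_coverage(psms, chains)
  if (nrow(psms) == 0) {
    return(structure(list(sites = empty_sites, coverage = cov),
                     class = "SiteCatalog"))
  }

  # long table of modified positions: one row per (psm, position, mod)
  modrows <- lapply(seq_len(nrow(psms)), function(i) {
    pm <- parse_mod_string(psms$mod_string[i])
    pm <- pm[pm$name %in% c("HyP", "HyK", "G-HyK", "GG-HyK"), , drop = FALSE]
    if (nrow(pm) == 0) return(NULL)
    data.frame(psm = i, chain_id = psms$chain_id[i],
               position = psms$start[i] + pm$relpos - 1L, name = pm$name,
               stringsAsFactors = FALSE)
  })
  ml <- do.call(rbind, Filter(Negate(is.null), modrows))
  if (is.null(ml) || nrow(ml) == 0) {
    return(structure(list(sites = empty_sites, coverage = cov),
                     class = "SiteCatalog"))
  }

  anns <- lapply(chains, annotate_motifs)
  site_key <- unique(ml[c("chain_id", "position")])
  rows <- vector("list", nrow(site_key))
  for (k in seq_len(nrow(site_key))) {
    cid <- site_key$chain_id[k]
    pos <- site_key$position[k]
    seq <- chain_sequence(chains[[cid]])
    residue <- substr(seq, pos, pos)
    ann <- anns[[cid]]
    mc <- ann$motif_class[match(pos, ann$position)]
    if (is.na(mc)) mc <- "NONE"
    here <- ml[ml$chain_id == cid & ml$position == pos, , drop = FALSE]
    counts <- table(factor(here$name, levels = c("HyP", "HyK", "G-HyK", "GG-HyK")))
    # unmodified support: PSMs covering the position with no mod on it
    covering <- which(psms$chain_id == cid & psms$start <= pos & psms$end >= pos)
    n_unmod <- sum(!(covering %in% here$psm))

    classification <- NA_character_
    if (residue == "P") {
      if (mc == "YAA_PRO") {
        classification <- "HYP4"
      } else if (mc == "XAA_PRO") {
        yaa <- pos + 1L
        yaa_is_p <- yaa <= nchar(seq) && substr(seq, yaa, yaa) == "P"
        if (yaa_is_p) {
          if (relaxed_hyp3) {
            yaa_hyp <- any(ml$chain_id == cid & ml$position == yaa &
                             ml$name == "HyP")
          } else {
            yaa_hyp <- any(vapply(unique(here$psm), function(i) {
              any(ml$psm == i & ml$position == yaa & ml$name == "HyP")
            }, logical(1)))
          }
          classification <- if (yaa_hyp) "HYP3" else "HYP_AMBIGUOUS"
        } else {
          classification <- "HYP_AMBIGUOUS"
        }
      } else {
        classification <- "HYP_AMBIGUOUS"
      }
    } else if (residue == "K") {
      classification <- "LYS_SITE"
    }

    states <- names(counts)[counts >= min_psms]
    if (n_unmod >= min_psms) states <- c("unmod", states)
    mature <- tryCatch(to_mature(chains[[cid]], pos), error = function(e) NA_integer_)
    rows[[k]] <- data.frame(
      chain_id = cid, position = pos, position_mature = mature,
      residue = residue, motif_class = mc, classification = classification,
      states = paste(states, collapse = ","),
      n_unmod = n_unmod,
      n_HyP = as.integer(counts[["HyP"]]),
      n_HyK = as.integer(counts[["HyK"]]),
      n_GHyK = as.integer(counts[["G-HyK"]]),
      n_GGHyK = as.integer(counts[["GG-HyK"]]),
      stringsAsFactors = FALSE
    )
  }
  sites <- do.call(rbind, rows)
  # drop sites whose every state fell below the support threshold
  keep <- nzchar(sites$states)
  sites <- sites[keep, , drop = FALSE]
  sites <- sites[order(sites$chain_id, sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  structure(list(sites = sites, coverage = cov), class = "SiteCatalog")
}

catalog_coverage <- function(psms, chains) {
  do.call(rbind, lapply(names(chains), function(cid) {
    cv <- tryCatch(sequence_coverage(psms, chains[[cid]]),
                   error = function(e) NA_real_)
    data.frame(chain_id = cid, coverage = cv, stringsAsFactors = FALSE)
  }))
}

#' @export
print.SiteCatalog <- function(x, ...) {
  cat("SiteCatalog: ", nrow(x$sites), " sites on ",
      length(unique(x$sites$chain_id)), " chain(s)\n", sep = "")
  invisible(x)
}

#' Percent sequence coverage of the mature chain
#'
#' 100 x (distinct mature positions covered by at least one identified
#' target peptide) / (mature chain length). Overlapping peptides count
#' positions once.
#'
#' @param psms Target PSM table.
#' @param chain A `CollagenChain` with the mature range annotated.
#' @return Coverage percent in `[0, 100]`.
#' @export
sequence_coverage <- function(psms, chain) {
  mr <- mature_range(chain)
  sub <- psms[psms$chain_id == chain$id & !psms$is_decoy, , drop = FALSE]
  if (nrow(sub) == 0) return(0)
  covered <- logical(mr[2] - mr[1] + 1L)
  for (i in seq_len(nrow(sub))) {
    a <- max(sub$start[i], mr[1])
    b <- min(sub$end[i], mr[2])
    if (a <= b) covered[(a:b) - mr[1] + 1L] <- TRUE
  }
  100 * sum(covered) / length(covered)
}

#' Table-1-style per-chain tallies of a site catalog
#'
#' Counts, per chain, the 3-hydroxyproline sites and the lysine sites
#' observed in each modification state. One lysine site showing
#' microheterogeneity contributes to every state column it was observed
#' in. Positions are deduplicated.
#'
#' @param catalog A `SiteCatalog`.
#' @return A data.frame with columns `chain_id`, `hyp3`, `hyk`, `ghyk`,
#'   `gghyk` and a final `TOTAL` row.
#' @export
tabulate_catalog <- function(catalog) {
  s <- unique(catalog$sites)
  chains <- unique(s$chain_id)
  per <- do.call(rbind, lapply(chains, function(cid) {
    sub <- s[s$chain_id == cid, , drop = FALSE]
    data.frame(
      chain_id = cid,
      hyp3 = sum(sub$classification == "HYP3", na.rm = TRUE),
      hyk = sum(sub$n_HyK > 0),
      ghyk = sum(sub$n_GHyK > 0),
      gghyk = sum(sub$n_GGHyK > 0),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(per)) {
    per <- data.frame(chain_id = character(0), hyp3 = integer(0),
                      hyk = integer(0), ghyk = integer(0), gghyk = integer(0))
  }
  rbind(per, data.frame(chain_id = "TOTAL", hyp3 = sum(per$hyp3),
                        hyk = sum(per$hyk), ghyk = sum(per$ghyk),
                        gghyk = sum(per$gghyk)))
}

#' Map conserved PTM sites between two chains
#'
#' A site pair is conserved when the two positions are aligned (no gap)
#' in the supplied pairwise alignment and both carry the requested
#' classification. Sites opposite a gap, or whose partner lacks the
#' classification, are reported as specific to their own chain.
#'
#' @param catalog_a,catalog_b `SiteCatalog` objects, each restricted to a
#'   single chain (or data.frames of sites with `position` and
#'   `classification` columns).
#' @param alignment A `ChainAlignment` of chain A (query) vs chain B
#'   (reference).
#' @param classification Site class to compare (default `"HYP3"`).
#' @return A list with `conserved` (data.frame `pos_a`, `pos_b`),
#'   `specific_a` and `specific_b` (integer position vectors).
#' @export
conserved_sites <- function(catalog_a, catalog_b, alignment,
                            classification = "HYP3") {
  if (is.null(alignment)) stop("an alignment between the chains is required")
  stopifnot(inherits(alignment, "ChainAlignment"))
  site_pos <- function(x) {
    s <- if (inherits(x, "SiteCatalog")) x$sites else x
    if (length(unique(s$chain_id)) > 1) {
      stop("conserved_sites expects single-chain catalogs")
    }
    sort(unique(s$position[s$classification == classification]))
  }
  pa <- site_pos(catalog_a)
  pb <- site_pos(catalog_b)
  mapped <- alignment$pairs$rpos[match(pa, alignment$pairs$qpos)]
  conserved <- !is.na(mapped) & mapped %in% pb
  list(
    conserved = data.frame(pos_a = pa[conserved], pos_b = mapped[conserved]),
    specific_a = pa[!conserved],
    specific_b = setdiff(pb, mapped[conserved])
  )
}

#' Write a site catalog as TSV
#' @param catalog A `SiteCatalog`.
#' @param path Output path.
#' @param comment Optional `#`-prefixed header comment.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(catalog$sites, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
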