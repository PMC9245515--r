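# Packaged transcriptions of the published zebrafish heart ECM collagen
# PTM catalogs and quantitation tables, with loaders and self-checks.

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "colptm")
  if (!nzchar(p)) stop("packaged fixture not found: ", name)
  p
}

#' Published zebrafish heart ECM collagen PTM site catalog
#'
#' The packaged transcription of the published per-chain site lists
#' (3-hydroxyproline, hydroxylysine, galactosyl- and
#' glucosylgalactosyl-hydroxylysine), one row per printed entry. One
#' glucosylgalactosyl-hydroxylysine entry (COL5A2a position 761) is
#' printed twice in the source and kept twice, flagged in `note`.
#'
#' @return A data.frame with `chain_id`, `category` (`HYP3`, `HYK`,
#'   `GHYK`, `GGHYK`), `position`, `note`.
#' @export
ptm_site_table <- function() {
  utils::read.delim(fixture_path("zebrafish_heart_ptm_sites.tsv"),
                    comment.char = "#", stringsAsFactors = FALSE, fill = TRUE)
}

#' Chains of the published site catalog
#' @return Character vector of the 23 catalog chain ids.
#' @export
ptm_catalog_chains <- function() {
  utils::read.delim(fixture_path("zebrafish_heart_collagen_chains.tsv"),
                    comment.char = "#", stringsAsFactors = FALSE)$chain_id
}

#' Tally the published site catalog
#'
#' Counts printed entries per chain and category, as the published table
#' totals do (i.e. without deduplicating the one repeated entry).
#'
#' @return A data.frame with per-chain counts (`hyp3`, `hyk`, `ghyk`,
#'   `gghyk`) and a `TOTAL` row.
#' @export
tabulate_ptm_site_table <- function() {
  tab <- ptm_site_table()
  chains <- ptm_catalog_chains()
  per <- do.call(rbind, lapply(chains, function(cid) {
    sub <- tab[tab$chain_id == cid, , drop = FALSE]
    data.frame(chain_id = cid,
               hyp3 = sum(sub$category == "HYP3"),
               hyk = sum(sub$category == "HYK"),
               ghyk = sum(sub$category == "GHYK"),
               gghyk = sum(sub$category == "GGHYK"),
               stringsAsFactors = FALSE)
  }))
  rbind(per, data.frame(chain_id = "TOTAL", hyp3 = sum(per$hyp3),
                        hyk = sum(per$hyk), ghyk = sum(per$ghyk),
                        gghyk = sum(per$gghyk)))
}

#' Conservation status of the COL1A1a 3-hydroxyproline sites
#'
#' The 24 catalog 3-HyP positions of zebrafish COL1A1a with their
#' published conservation status against re-analyzed human and mouse
#' heart COL1A1 (10 conserved, 14 zebrafish-specific). The
#' `reference_position` column is a synthetic identity mapping standing
#' in for the unpublished human/mouse coordinates.
#'
#' @return A data.frame with `position`, `status`, `reference_position`.
#' @export
hyp3_conservation_table <- function() {
  utils::read.delim(fixture_path("col1a1a_hyp3_conservation.tsv"),
                    comment.char = "#", stringsAsFactors = FALSE)
}

#' Published 3-hydroxyproline occupancy table
#' @return Long data.frame: `chain_id`, `site`, `condition`, `mean`, `sd`.
#' @export
hyp3_occupancy_table <- function() {
  utils::read.delim(fixture_path("hyp3_occupancy_table.tsv"),
                    comment.char = "#", stringsAsFactors = FALSE)
}

#' Published lysine microheterogeneity table
#' @return Long data.frame: `chain_id`, `site`, `state`, `condition`,
#'   `mean`, `sem`, `significant`; not-detected states carry `NA`.
#' @export
microheterogeneity_table <- function() {
  utils::read.delim(fixture_path("lysine_microheterogeneity_table.tsv"),
                    comment.char = "#", stringsAsFactors = FALSE)
}

#' Self-check of the microheterogeneity table row sums
#'
#' For every (site, condition) the printed state percents (ignoring
#' not-detected states) should sum to 100. Returns the per-row sums with
#' a flag at the given tolerance, so printed-rounding discrepancies in
#' the source are visible rather than silently absorbed.
#'
#' @param tol Allowed deviation from 100 (default 0.1).
#' @return A data.frame with `chain_id`, `site`, `condition`, `total`,
#'   `within_tol`.
#' @export
check_microheterogeneity_sums <- function(tol = 0.1) {
  tab <- microheterogeneity_table()
  key <- unique(tab[c("chain_id", "site", "condition")])
  key$total <- vapply(seq_len(nrow(key)), function(i) {
    sub <- tab[tab$chain_id == key$chain_id[i] & tab$site == key$site[i] &
                 tab$condition == key$condition[i], , drop = FALSE]
    sum(sub$mean, na.rm = TRUE)
  }, numeric(1))
  key$within_tol <- abs(key$total - 100) <= tol
  rownames(key) <- NULL
  key
}

#' Published collagen I cleavage-site coordinates
#' @return A data.frame with `chain_id`, `segment`, `start`, `end`.
#' @export
col1_cleavage_table <- function() {
  utils::read.delim(fixture_path("col1_cleavage_sites.tsv"),
                    comment.char = "#", stringsAsFactors = FALSE)
}
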