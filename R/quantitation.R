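#' Normalize spectral counts to the mean file depth
#'
#' Scales each sample's raw spectral counts by (global mean file total /
#' file total), so normalized values stay on the counts scale and the
#' "at least 3 normalized counts" heatmap-eligibility threshold remains
#' meaningful. A `"fraction"` alternative divides by the file total
#' instead.
#'
#' @param counts Numeric matrix, rows = protein groups, columns = samples
#'   (raw spectral counts).
#' @param method `"mean-depth"` (default) or `"fraction"`.
#' @return A matrix of normalized counts with the per-sample raw totals
#'   attached as attribute `"raw_totals"`.
#' @export
normalize_spectral_counts <- function(counts, method = c("mean-depth", "fraction")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  totals <- colSums(counts)
  if (any(totals <= 0)) {
    bad <- colnames(counts)[totals <= 0]
    if (is.null(bad)) bad <- which(totals <= 0)
    stop("zero total spectral counts in file(s): ", paste(bad, collapse = ", "))
  }
  factor <- switch(method,
    "mean-depth" = mean(totals) / totals,
    "fraction" = 1 / totals
  )
  out <- sweep(counts, 2, factor, `*`)
  attr(out, "raw_totals") <- totals
  out
}

#' Rows eligible for heatmap display
#'
#' A protein group qualifies when it reaches at least `min_count`
#' normalized spectral counts in at least one sample.
#'
#' @param mat Normalized count matrix.
#' @param min_count Eligibility threshold (default 3).
#' @return The filtered matrix.
#' @export
heatmap_eligible <- function(mat, min_count = 3) {
  mat[apply(mat, 1, max) >= min_count, , drop = FALSE]
}

#' Fold change of condition means against a baseline
#'
#' Ratio of the condition mean to the baseline mean, with percent change
#' expressed as `(1 - ratio) * 100` when the ratio is below 1 (a ratio of
#' 0.68 is a 32 percent decrease). A zero baseline yields `NA`.
#'
#' @param mat Normalized abundance matrix.
#' @param condition_cols Column names/indices of the condition samples.
#' @param baseline_cols Column names/indices of the baseline (e.g. sham)
#'   samples.
#' @return A data.frame with `ratio` and `percent_change` per row
#'   (positive percent = decrease, negative = increase).
#' @export
fold_change <- function(mat, condition_cols, baseline_cols) {
  mat <- as.matrix(mat)
  cm <- rowMeans(mat[, condition_cols, drop = FALSE])
  bm <- rowMeans(mat[, baseline_cols, drop = FALSE])
  ratio <- ifelse(bm > 0, cm / bm, NA_real_)
  data.frame(ratio = ratio, percent_change = (1 - ratio) * 100,
             row.names = rownames(mat))
}

#' Row-standardized heatmap matrix
#'
#' Per-row z-scores `(x - row mean) / row SD`, clipped to `[-2, +2]`;
#' constant rows map to 0.
#'
#' @param mat Numeric matrix with at least two columns.
#' @return The standardized, clipped matrix.
#' @export
heatmap_matrix <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("heatmap standardization needs >= 2 columns")
  z <- t(apply(mat, 1, function(x) {
    s <- sqrt(mean((x - mean(x))^2)) # population SD
    if (!is.finite(s) || s == 0) return(rep(0, length(x)))
    (x - mean(x)) / s
  }))
  dimnames(z) <- dimnames(mat)
  pmin(pmax(z, -2), 2)
}

check_feature_table <- function(features) {
  need <- c("peptidoform", "chain_id", "position", "state", "condition",
            "replicate", "area")
  miss <- setdiff(need, names(features))
  if (length(miss) > 0) {
    stop("feature table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (any(features$area < 0, na.rm = TRUE)) stop("areas must be >= 0")
  if (!"ambiguous" %in% names(features)) features$ambiguous <- FALSE
  features
}

#' MS1-area modification-state occupancy at a site
#'
#' For each replicate of each condition, the percent of the site's total
#' MS1 area carried by each modification state:
#' `100 * sum(areas of peptidoforms in that state) / sum(areas over all
#' states)`. Peptidoforms whose state at the site is ambiguous
#' (unlocalized) are excluded by default, or split equally across their
#' candidate states with `apportion_equal = TRUE` (ambiguous rows carry a
#' `|`-separated state string). Replicates whose total area is zero are
#' not detected (ND); if every replicate of a condition is ND the record
#' is returned with `NA` percents. Percents are then summarized as mean
#' with SD (`dispersion = "sd"`, occupancy-table style) or SEM
#' (`"sem"`, microheterogeneity-table style) across detected replicates.
#'
#' @param features MS1 feature table: columns `peptidoform`, `chain_id`,
#'   `position`, `state`, `condition`, `replicate`, `area`, optional
#'   `ambiguous`.
#' @param chain_id,position The queried site.
#' @param dispersion `"sd"` or `"sem"`.
#' @param apportion_equal Split ambiguous-state areas equally instead of
#'   excluding them.
#' @return A data.frame with one row per (condition, state): `mean`,
#'   `dispersion`, `n_replicates`, `nd` flag, plus a
#'   `"replicates"` attribute holding the per-replicate percents.
#' @export
site_occupancy <- function(features, chain_id, position,
                           dispersion = c("sd", "sem"),
                           apportion_equal = FALSE) {
  dispersion <- match.arg(dispersion)
  features <- check_feature_table(features)
  sub <- features[features$chain_id == chain_id &
                    features$position == position, , drop = FALSE]
  if (nrow(sub) == 0) stop("no features for site ", chain_id, ":", position)
  amb <- grepl("|", sub$state, fixed = TRUE) | sub$ambiguous
  if (apportion_equal && any(amb)) {
    split_rows <- lapply(which(amb), function(i) {
      states <- strsplit(sub$state[i], "|", fixed = TRUE)[[1]]
      out <- sub[rep(i, length(states)), , drop = FALSE]
      out$state <- states
      out$area <- out$area / length(states)
      out$ambiguous <- FALSE
      out
    })
    sub <- rbind(sub[!amb, , drop = FALSE], do.call(rbind, split_rows))
  } else {
    sub <- sub[!amb, , drop = FALSE]
  }
  if (nrow(sub) == 0) stop("all features at site ", chain_id, ":", position,
                           " are ambiguous")
  occupancy_summarize(sub, dispersion)
}

occupancy_summarize <- function(sub, dispersion, states = NULL) {
  conditions <- unique(sub$condition)
  if (is.null(states)) states <- unique(sub$state)
  reps <- list()
  out <- list()
  for (cond in conditions) {
    cc <- sub[sub$condition == cond, , drop = FALSE]
    reptab <- list()
    for (r in unique(cc$replicate)) {
      rr <- cc[cc$replicate == r, , drop = FALSE]
      tot <- sum(rr$area)
      if (tot <= 0) next # replicate not detected
      pct <- vapply(states, function(st) {
        100 * sum(rr$area[rr$state == st]) / tot
      }, numeric(1))
      reptab[[as.character(r)]] <- pct
    }
    if (length(reptab) == 0) {
      out[[cond]] <- data.frame(condition = cond, state = states,
                                mean = NA_real_, dispersion = NA_real_,
                                n_replicates = 0L, nd = TRUE,
                                stringsAsFactors = FALSE)
      next
    }
    m <- do.call(rbind, reptab) # replicates x states
    mu <- colMeans(m)
    dd <- apply(m, 2, stats::sd)
    if (dispersion == "sem") dd <- dd / sqrt(nrow(m))
    if (nrow(m) == 1) dd <- rep(NA_real_, ncol(m))
    out[[cond]] <- data.frame(condition = cond, state = states,
                              mean = as.numeric(mu), dispersion = as.numeric(dd),
                              n_replicates = nrow(m), nd = FALSE,
                              stringsAsFactors = FALSE)
    reps[[cond]] <- m
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "replicates") <- reps
  res
}

#' Joint occupancy of a co-resident site cluster
#'
#' Treats a set of sites carried on the same peptidoforms as one unit:
#' a peptidoform counts as "modified" when any cluster site deviates from
#' the unmodified state, and the same area arithmetic as
#' [site_occupancy()] is applied to the modified-vs-unmodified split. The
#' cluster percent is therefore at least the largest individual site
#' percent.
#'
#' @inheritParams site_occupancy
#' @param positions Integer vector of cluster site positions.
#' @return As [site_occupancy()], with states `"modified"`/`"unmod"`.
#' @export
cluster_occupancy <- function(features, chain_id, positions,
                              dispersion = c("sd", "sem")) {
  dispersion <- match.arg(dispersion)
  features <- check_feature_table(features)
  sub <- features[features$chain_id == chain_id &
                    features$position %in% positions &
                    !features$ambiguous, , drop = FALSE]
  if (nrow(sub) == 0) stop("no features for cluster ", chain_id, ":",
                           paste(positions, collapse = ","))
  # collapse to one row per peptidoform x condition x replicate
  key <- interaction(sub$peptidoform, sub$condition, sub$replicate, drop = TRUE)
  rows <- lapply(split(sub, key), function(g) {
    data.frame(peptidoform = g$peptidoform[1], chain_id = chain_id,
               position = positions[1],
               state = if (any(g$state != "unmod")) "modified" else "unmod",
               condition = g$condition[1], replicate = g$replicate[1],
               area = g$area[1], stringsAsFactors = FALSE)
  })
  collapsed <- do.call(rbind, rows)
  occupancy_summarize(collapsed, dispersion, states = c("modified", "unmod"))
}

#' Classical one-way ANOVA across conditions
#'
#' Per-replicate percents are compared across conditions with a one-way
#' analysis of variance; significance is flagged at p < 0.05. Degenerate
#' inputs follow fixed conventions: fewer than 2 groups with at least 2
#' values each is reported untestable; identical values everywhere
#' (zero total variance) is reported as p = 1.
#'
#' @param values Numeric vector of per-replicate percents.
#' @param groups Factor/vector of condition labels, same length.
#' @return A list with `F`, `p`, `significant`, `testable`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- as.factor(groups)
  ok <- is.finite(values)
  values <- values[ok]
  groups <- droplevels(groups[ok])
  sizes <- table(groups)
  if (length(sizes) < 2 || sum(sizes >= 2) < 2) {
    return(list(F = NA_real_, p = NA_real_, significant = NA, testable = FALSE))
  }
  if (stats::var(values) == 0) {
    return(list(F = NA_real_, p = 1, significant = FALSE, testable = TRUE))
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  Fv <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  list(F = Fv, p = p, significant = is.finite(p) && p < 0.05, testable = TRUE)
}

#' Write an MS1 feature or occupancy table as TSV
#' @param x A data.frame.
#' @param path Output path.
#' @param comment Optional `#`-prefixed header comment.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an MS1 feature table from TSV
#' @param path TSV path with the columns described in [site_occupancy()].
#' @return A validated data.frame.
#' @export
read_feature_table <- function(path) {
  check_feature_table(utils::read.delim(path, stringsAsFactors = FALSE,
                                        comment.char = "#"))
}
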