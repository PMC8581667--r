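# Hierarchical image-cytometry gating: first-match-wins walk of an ordered
# rule list of marker-positivity conjunctions.

default_gating_rules <- function(variant) {
  if (variant == "discovery") list(
    list(label = "cd8_t", pos = c("CD45", "CD3", "CD8"), neg = character(0)),
    list(label = "treg", pos = c("CD45", "CD3", "Foxp3"), neg = "CD8"),
    list(label = "helper_t", pos = c("CD45", "CD3"), neg = c("CD8", "Foxp3"),
         subtypes = c(th1 = "Tbet", th2 = "GATA3")),
    list(label = "b_cell", pos = c("CD45", "CD20"), neg = "CD3"),
    list(label = "nk", pos = c("CD45", "CD56"), neg = c("CD3", "CD20")),
    list(label = "granulocyte", pos = c("CD45", "CD66b"),
         neg = c("CD3", "CD20", "CD56")),
    list(label = "mast", pos = c("CD45", "Tryptase"),
         neg = c("CD3", "CD20", "CD56", "CD66b")),
    list(label = "tam", pos = c("CD45", "CD68", "CSF1R"),
         neg = c("CD3", "CD20", "CD56", "CD66b", "Tryptase"),
         split = list(marker = "CD163", pos_label = "tam_cd163pos",
                      neg_label = "tam_cd163neg"))
  ) else list(
    list(label = "cd8_t", pos = c("CD3", "CD8"), neg = character(0)),
    list(label = "treg", pos = c("CD3", "CD4", "Foxp3"), neg = "CD8"),
    list(label = "helper_t", pos = c("CD3", "CD4"), neg = c("CD8", "Foxp3"))
  )
}

#' Gating configuration for lineage classification
#'
#' Bundles per-marker positivity thresholds with an ordered rule list.
#' Rules are conjunctions of marker requirements (`pos` markers at or
#' above threshold, `neg` markers below), resolved first-match-wins so
#' rule order, not error handling, prevents overlaps. The discovery
#' variant implements the CD8/Foxp3-based hierarchy (CD8 T, TREG, helper T
#' with TH1/Tbet and TH2/GATA3 sub-labels, B, NK, granulocyte, mast, TAM
#' split by CD163); the validation variant identifies helper T as CD3+CD4+
#' (Foxp3- vs Foxp3+ for TREG). PD-1 status is flagged independently of
#' lineage.
#'
#' @param variant `"discovery"` or `"validation"`.
#' @param thresholds Named numeric positivity thresholds per marker;
#'   defaults to 127 for every panel marker.
#' @param rules Optional custom rule list overriding the variant default.
#' @param pd1_marker Marker used for the PD-1 flag (default `"PD1"`).
#' @return An object of class `gating_config`.
#' @export
gating_config <- function(variant = c("discovery", "validation"),
                          thresholds = NULL, rules = NULL,
                          pd1_marker = "PD1") {
  variant <- match.arg(variant)
  panel <- default_marker_panel(variant)
  if (is.null(thresholds)) thresholds <- setNames(rep(127, length(panel)), panel)
  if (is.null(rules)) rules <- default_gating_rules(variant)
  used <- unique(unlist(lapply(rules, function(r)
    c(r$pos, r$neg, r$subtypes, if (!is.null(r$split)) r$split$marker))))
  missing <- setdiff(used, names(thresholds))
  if (length(missing))
    stop("rules reference markers without thresholds: ",
         paste(missing, collapse = ", "))
  structure(list(variant = variant, thresholds = thresholds, rules = rules,
                 pd1_marker = pd1_marker),
            class = "gating_config")
}

#' Data-driven per-marker thresholds (Otsu on per-cell intensities)
#'
#' Alternative to the fixed default of 127: estimates each marker's
#' positivity threshold by Otsu's method on the distribution of per-cell
#' mean intensities. Markers whose distribution is degenerate keep the
#' fallback value.
#'
#' @param table A `cell_table`.
#' @param markers Markers to calibrate.
#' @param fallback Threshold used when no split exists (default 127).
#' @return Named numeric vector of thresholds.
#' @export
otsu_cell_thresholds <- function(table, markers, fallback = 127) {
  vapply(setNames(markers, markers), function(mk) {
    v <- table[[mk]]
    if (is.null(v)) stop("marker absent from table: ", mk)
    h <- intensity_histogram(v[is.finite(v)])
    if (sum(h > 0) < 2L) fallback else as.numeric(otsu_from_histogram(h))
  }, numeric(1))
}

#' Classify cells into immune lineages by hierarchical gating
#'
#' Walks the configured rule list first-match-wins: a cell gets the label
#' of the first rule whose positive markers are all at or above their
#' thresholds and whose negative markers are all below. Helper T cells are
#' sub-labeled TH1 (Tbet+) or TH2 (GATA3+, Tbet taking precedence when
#' both); TAM are split by CD163. Unmatched cells are labeled `"other"`.
#' PD-1 positivity is flagged in an independent `pd1` column.
#'
#' @param table A `cell_table` with one mean-intensity column per marker.
#' @param config A `gating_config` consistent with the table's panel.
#' @return The table with `lineage` (finest granularity: th1, th2,
#'   helper_t, tam_cd163pos, ...) and logical `pd1` columns appended.
#' @export
classify_cells <- function(table, config = gating_config("discovery")) {
  stopifnot(is.data.frame(table), inherits(config, "gating_config"))
  used <- unique(unlist(lapply(config$rules, function(r)
    c(r$pos, r$neg, r$subtypes, if (!is.null(r$split)) r$split$marker))))
  missing <- setdiff(used, names(table))
  if (length(missing))
    stop("panel mismatch: table lacks markers: ",
         paste(missing, collapse = ", "), call. = FALSE)
  n <- nrow(table)
  pos_mat <- vapply(used, function(mk)
    table[[mk]] >= config$thresholds[[mk]], logical(n))
  pos_mat <- matrix(pos_mat, nrow = n, dimnames = list(NULL, used))
  lineage <- rep("other", n)
  assigned <- rep(FALSE, n)
  for (rule in config$rules) {
    ok <- !assigned
    for (mk in rule$pos) ok <- ok & pos_mat[, mk]
    for (mk in rule$neg) ok <- ok & !pos_mat[, mk]
    if (!any(ok)) next
    lab <- rep(rule$label, sum(ok))
    if (!is.null(rule$split)) {
      sp <- pos_mat[ok, rule$split$marker]
      lab <- ifelse(sp, rule$split$pos_label, rule$split$neg_label)
    }
    if (!is.null(rule$subtypes)) {
      sub <- rep(rule$label, sum(ok))
      done <- rep(FALSE, sum(ok))
      for (st in names(rule$subtypes)) {
        hit <- !done & pos_mat[ok, rule$subtypes[[st]]]
        sub[hit] <- st
        done <- done | hit
      }
      lab <- sub
    }
    lineage[ok] <- lab
    assigned <- assigned | ok
  }
  out <- table
  out$lineage <- lineage
  out$pd1 <- if (config$pd1_marker %in% names(table))
    table[[config$pd1_marker]] >= config$thresholds[[config$pd1_marker]]
  else rep(NA, n)
  out
}

# lineages counted as helper T in aggregate metrics
helper_lineages <- c("helper_t", "th1", "th2")
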