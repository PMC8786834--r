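check_cell_table <- function(cells) {
  if (!is.data.frame(cells) || !nrow(cells)) stop("empty cell table")
  if (!"compartment" %in% names(cells)) stop("cell table lacks a compartment column")
  invisible(cells)
}

select_compartment <- function(cells, compartment) {
  if (identical(compartment, "all")) return(cells)
  sub <- cells[cells$compartment == compartment, , drop = FALSE]
  if (!nrow(sub)) stop("empty compartment selection: ", compartment)
  sub
}

#' Percentage of marker-positive cells
#'
#' A cell is positive when its staining category is weak, moderate or strong
#' (any non-negative category; no intensity weighting). For nuclear HIF-1alpha
#' the same rule applies to the nuclear staining category column.
#'
#' @param cells A `"cell_table"` (or any data frame with a `compartment`
#'   column and the marker column as a staining factor).
#' @param marker Column name, e.g. `"MCT1"`, `"MCT4"`, `"HIF1A_nuclear"`.
#' @param compartment `"epithelial"`, `"stromal"` or `"all"`.
#' @return Percentage in [0, 100].
#' @export
percent_positive <- function(cells, marker, compartment = "all") {
  check_cell_table(cells)
  if (!marker %in% names(cells)) stop("unknown marker column: ", marker)
  sub <- select_compartment(cells, compartment)
  100 * mean(sub[[marker]] != "negative")
}

#' Epithelium-to-stroma MCT4 ratio
#'
#' Ratio of the epithelial to the stromal percentage of MCT4-positive cells.
#' A zero stromal percentage makes the ratio undefined; it is returned as NA
#' with a warning rather than silently infinite.
#'
#' @param cells A `"cell_table"` with both compartments present.
#' @return Dimensionless ratio (0 when the epithelial percentage is 0).
#' @export
mct4_epi_stroma_ratio <- function(cells) {
  epi <- percent_positive(cells, "MCT4", "epithelial")
  str_ <- percent_positive(cells, "MCT4", "stromal")
  if (str_ == 0) {
    warning("stromal MCT4 percentage is zero: ratio undefined")
    return(NA_real_)
  }
  epi / str_
}

#' Combined epithelial LDH expression
#'
#' Sum of all LDHA and LDHB transcript copies detected in epithelial cells of
#' the ROI (the quantity used for correlation testing), also reported per
#' epithelial cell for cross-ROI comparability.
#'
#' @param cells A `"cell_table"` with >= 1 epithelial cell and integer
#'   `LDHA`, `LDHB` columns.
#' @return List with `total` (copies) and `per_cell` (copies/cell).
#' @export
combined_epithelial_ldh <- function(cells) {
  epi <- select_compartment(check_cell_table(cells), "epithelial")
  total <- sum(epi$LDHA) + sum(epi$LDHB)
  list(total = total, per_cell = total / nrow(epi))
}

#' Expression ratios of mean copies per cell
#'
#' LDHA/LDHB and LDHA/PDHA1 ratios of mean transcript copies per cell within
#' a compartment; the latter indexes glycolytic versus oxidative metabolism.
#' Zero-mean denominators are flagged (NA with a warning).
#'
#' @param cells A `"cell_table"`.
#' @param compartment `"epithelial"` (default), `"stromal"` or `"all"`.
#' @return Named list: `LDHA_LDHB`, `LDHA_PDHA1`.
#' @export
expression_ratios <- function(cells, compartment = "epithelial") {
  sub <- select_compartment(check_cell_table(cells), compartment)
  ratio <- function(num, den) {
    m <- mean(sub[[den]])
    if (m == 0) {
      warning("zero mean ", den, ": ratio undefined")
      return(NA_real_)
    }
    mean(sub[[num]]) / m
  }
  list(LDHA_LDHB = ratio("LDHA", "LDHB"),
       LDHA_PDHA1 = ratio("LDHA", "PDHA1"))
}

#' Epithelial and stromal cell counts
#'
#' @param cells A non-empty `"cell_table"`.
#' @return List with `epithelial`, `stromal` and the epithelium-to-stroma
#'   count `ratio` (NA with a warning when no stromal cells are present).
#' @export
cell_counts <- function(cells) {
  check_cell_table(cells)
  epi <- sum(cells$compartment == "epithelial")
  str_ <- sum(cells$compartment == "stromal")
  ratio <- if (str_ == 0) {
    warning("no stromal cells: count ratio undefined")
    NA_real_
  } else epi / str_
  list(epithelial = epi, stromal = str_, ratio = ratio)
}

#' Full compartmentalised summary of one cell table
#'
#' Every per-ROI histology biomarker in one row: per-compartment percent
#' positive for each marker, the epithelium-to-stroma MCT4 ratio, cell
#' counts, per-compartment mean copies per cell per gene, combined
#' epithelial LDH (total and per cell), and the LDHA/LDHB and LDHA/PDHA1
#' epithelial ratios.
#'
#' @param cells A `"cell_table"`.
#' @return Named list (one scalar per metric) suitable for
#'   `as.data.frame()`.
#' @export
compartment_summary <- function(cells) {
  check_cell_table(cells)
  counts <- cell_counts(cells)
  ldh <- combined_epithelial_ldh(cells)
  ratios <- expression_ratios(cells, "epithelial")
  out <- list(
    n_epithelial = counts$epithelial,
    n_stromal = counts$stromal,
    epi_stroma_count_ratio = counts$ratio)
  for (mk in intersect(c("MCT1", "MCT4", "HIF1A_nuclear"), names(cells))) {
    out[[paste0(mk, "_pct_epi")]] <- percent_positive(cells, mk, "epithelial")
    out[[paste0(mk, "_pct_stroma")]] <- percent_positive(cells, mk, "stromal")
    out[[paste0(mk, "_pct_all")]] <- percent_positive(cells, mk, "all")
  }
  out$MCT4_epi_stroma_ratio <- mct4_epi_stroma_ratio(cells)
  for (gn in intersect(c("LDHA", "LDHB", "PDHA1"), names(cells))) {
    epi <- cells[cells$compartment == "epithelial", gn]
    str_ <- cells[cells$compartment == "stromal", gn]
    out[[paste0(gn, "_mean_epi")]] <- mean(epi)
    out[[paste0(gn, "_mean_stroma")]] <- if (length(str_)) mean(str_) else NA_real_
  }
  out$combined_LDH_epi_total <- ldh$total
  out$combined_LDH_epi_per_cell <- ldh$per_cell
  out$LDHA_LDHB_epi <- ratios$LDHA_LDHB
  out$LDHA_PDHA1_epi <- ratios$LDHA_PDHA1
  out
}
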