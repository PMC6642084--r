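#' Read a lipid abundance table
#'
#' Rows are (sample, lipid class, lipid species, abundance), with
#' abundances as extracted-ion-chromatogram areas under the curve (AUC)
#' from LC-MS. Only the two classes compared here, `PC`
#' (phosphatidylcholine) and `DGTS` (diacylglyceryl-trimethylhomoserine),
#' are permitted.
#'
#' @param path TSV file with columns `sample_id`, `lipid_class`,
#'   `species_id`, `abundance`.
#' @return Tibble with those four columns, `abundance` numeric >= 0.
#' @export
load_lipids <- function(path) {
  if (!file.exists(path)) {
    stop_input("lipid table not found: ", path)
  }
  lt <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    comment = "#", progress = FALSE
  )
  required <- c("sample_id", "lipid_class", "species_id", "abundance")
  missing <- setdiff(required, names(lt))
  if (length(missing)) {
    stop_input("lipid table ", path, " is missing required column(s): ",
               paste(missing, collapse = ", "))
  }
  ab <- suppressWarnings(as.numeric(lt$abundance))
  if (any(is.na(ab) | ab < 0)) {
    stop_input("lipid table ", path,
               " has missing/negative abundances at data row(s): ",
               paste(head(which(is.na(ab) | ab < 0), 5L), collapse = ", "))
  }
  bad <- setdiff(unique(lt$lipid_class), c("PC", "DGTS"))
  if (length(bad)) {
    stop_input("lipid_class must be PC or DGTS; found: ",
               paste(bad, collapse = ", "))
  }
  tibble::tibble(sample_id = lt$sample_id, lipid_class = lt$lipid_class,
                 species_id = lt$species_id, abundance = ab)
}

lipid_totals <- function(table) {
  samples <- unique(table$sample_id)
  tot <- function(class) {
    vapply(samples, function(s) {
      sum(table$abundance[table$sample_id == s & table$lipid_class == class])
    }, 0)
  }
  dgts <- tot("DGTS")
  pc <- tot("PC")
  tibble::tibble(
    sample_id = samples,
    dgts_total = dgts,
    pc_total = pc,
    ratio = ifelse(pc > 0, dgts / pc, NA_real_),
    undefined = pc == 0
  )
}

#' DGTS/PC abundance ratio for one sample
#'
#' The ratio of the total DGTS abundance (sum of AUCs over DGTS species)
#' to the total PC abundance. When the PC total is zero the ratio is
#' undefined (including 0/0) and `NA` is returned with attribute
#' `undefined = TRUE`.
#'
#' @param table Lipid table as returned by [load_lipids()].
#' @param sample_id A sample present in the table.
#' @return A single non-negative number, or `NA` flagged `undefined`.
#' @seealso [dgts_pc_ratios()] for all samples at once.
#' @export
dgts_pc_ratio <- function(table, sample_id) {
  if (!sample_id %in% table$sample_id) {
    stop_input("sample not in the lipid table: ", sample_id)
  }
  tt <- lipid_totals(table[table$sample_id == sample_id, ])
  structure(tt$ratio[1L], undefined = tt$undefined[1L])
}

#' @rdname dgts_pc_ratio
#' @export
dgts_pc_ratios <- function(table) {
  lipid_totals(table)
}

#' Validate a sequence marker against lipid measurements
#'
#' Tests whether presence of a marker HMM in the transcriptome (e.g.
#' Pfam DUF3419, associated with DGTS synthase) predicts detectable DGTS in
#' the lipid extract of the same strain. A sample is lipid-positive when
#' its total DGTS abundance exceeds `detect_threshold` (default 0: any
#' nonzero AUC counts as detected). The 2x2 table of marker vs lipid status
#' is tested with the exact two-sided Fisher test.
#'
#' Samples missing from either data source are dropped with a warning.
#'
#' @param presence Named 0/1 vector: one presence-matrix column for the
#'   marker HMM (`matrix[, "marker"]`).
#' @param table Lipid table as returned by [load_lipids()].
#' @param detect_threshold DGTS AUC above which DGTS counts as detected.
#' @return Object of class `marker_validation`: 2x2 counts
#'   (`n_marker_lipid`, `n_marker_only`, `n_lipid_only`, `n_neither`),
#'   `p_value`, `log10_p`, and the per-sample `ratios` tibble.
#' @export
validate_marker <- function(presence, table, detect_threshold = 0) {
  if (is.null(names(presence))) {
    stop_param("presence must be a named 0/1 vector (a presence-matrix column)")
  }
  tot <- lipid_totals(table)
  common <- intersect(names(presence), tot$sample_id)
  dropped <- c(setdiff(names(presence), common),
               setdiff(tot$sample_id, common))
  if (length(common) == 0L) {
    stop_input("no samples with both a presence call and lipid data")
  }
  if (length(dropped)) {
    warn(paste0("dropping ", length(dropped),
                " sample(s) missing from one data source: ",
                paste(dropped, collapse = ", ")))
  }
  marker <- presence[common] == 1L
  lipid <- tot$dgts_total[match(common, tot$sample_id)] > detect_threshold
  n_ml <- sum(marker & lipid)
  n_m <- sum(marker & !lipid)
  n_l <- sum(!marker & lipid)
  n_n <- sum(!marker & !lipid)
  ft <- fisher_2x2(n_ml, n_m, n_l, n_n)
  structure(
    list(n_marker_lipid = n_ml, n_marker_only = n_m,
         n_lipid_only = n_l, n_neither = n_n,
         p_value = ft$p_value, log10_p = ft$log10_p,
         detect_threshold = detect_threshold,
         ratios = tot[match(common, tot$sample_id), ]),
    class = "marker_validation"
  )
}

#' @export
print.marker_validation <- function(x, ...) {
  cat("marker vs DGTS 2x2 (marker+/lipid+, marker+/lipid-, marker-/lipid+, marker-/lipid-):\n")
  cat(sprintf("  %d, %d, %d, %d\n", x$n_marker_lipid, x$n_marker_only,
              x$n_lipid_only, x$n_neither))
  cat(sprintf("  two-sided exact p = %.6g\n", x$p_value))
  invisible(x)
}
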