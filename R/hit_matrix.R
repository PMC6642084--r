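#' Read a profile-HMM hit table
#'
#' Reads a tab-separated table of profile-HMM matches against de novo
#' transcriptome assemblies. Each row is one match of one HMM to one
#' transcript of one sample, with its bitscore (a log2-scaled
#' likelihood-ratio score). Multiple rows per (sample, hmm, transcript) are
#' allowed: HMM searches routinely emit several domain-level matches.
#'
#' Lines starting with `#` are treated as comments and skipped, so tables
#' written by [generate_dataset()] (which record their provenance in a
#' header comment) read back directly.
#'
#' @param path Path to a TSV file with columns `sample_id`, `hmm_id`,
#'   `transcript_id`, `bitscore` (UTF-8, `.` decimal separator).
#' @return A tibble of hit records with `bitscore` parsed as numeric.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("sample_id\thmm_id\ttranscript_id\tbitscore",
#'              "s1\th1\tt1\t42.5"), tf)
#' load_hits(tf)
load_hits <- function(path) {
  if (!file.exists(path)) {
    stop_input("hit table not found: ", path)
  }
  hits <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    comment = "#", na = character(), progress = FALSE
  )
  required <- c("sample_id", "hmm_id", "transcript_id", "bitscore")
  missing <- setdiff(required, names(hits))
  if (length(missing)) {
    stop_input("hit table ", path, " is missing required column(s): ",
               paste(missing, collapse = ", "))
  }
  scores <- suppressWarnings(as.numeric(hits$bitscore))
  bad <- which(is.na(scores) | !is.finite(scores))
  if (length(bad)) {
    stop_input("unparseable bitscore in ", path, " at data row(s): ",
               paste(head(bad, 5L), collapse = ", "),
               if (length(bad) > 5L) ", ..." else "")
  }
  tibble::tibble(
    sample_id = hits$sample_id,
    hmm_id = hits$hmm_id,
    transcript_id = hits$transcript_id,
    bitscore = scores
  )
}

#' Read a clade map
#'
#' Reads the assignment of samples to named groups (major clades, or tree
#' clusters). Every sample must carry exactly one label.
#'
#' @param path TSV file with columns `sample_id`, `clade`.
#' @return A tibble with columns `sample_id` and `clade`.
#' @export
load_clades <- function(path) {
  if (!file.exists(path)) {
    stop_input("clade map not found: ", path)
  }
  cl <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    comment = "#", progress = FALSE
  )
  missing <- setdiff(c("sample_id", "clade"), names(cl))
  if (length(missing)) {
    stop_input("clade map ", path, " is missing required column(s): ",
               paste(missing, collapse = ", "))
  }
  dup <- unique(cl$sample_id[duplicated(cl$sample_id)])
  if (length(dup)) {
    stop_input("clade map assigns multiple labels to sample(s): ",
               paste(dup, collapse = ", "))
  }
  tibble::tibble(sample_id = cl$sample_id, clade = cl$clade)
}

#' Call gene presence/absence from HMM bitscores
#'
#' A sample is called positive for an HMM when at least one of its
#' transcripts matches that HMM with a bitscore strictly greater than
#' `threshold` (default 10 bits, the conventional cutoff for these
#' searches; the strict inequality is a documented, configurable choice).
#' Samples listed in `samples` but absent from the hit table are retained
#' as all-zero rows: non-detection is treated as absence.
#'
#' @param hits Tibble of hit records as returned by [load_hits()].
#' @param threshold Calling threshold in bits; a hit counts when
#'   `bitscore > threshold`.
#' @param samples Sample ids defining the matrix rows; defaults to the
#'   samples seen in `hits`.
#' @param hmms HMM ids defining the matrix columns; defaults to the HMMs
#'   seen in `hits`.
#' @return A `presence_matrix`: an integer 0/1 matrix (samples x HMMs) with
#'   a `rule` attribute recording the calling rule.
#' @export
presence_call <- function(hits, threshold = 10,
                          samples = NULL, hmms = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold)) {
    stop_param("threshold must be a single finite number")
  }
  samples <- samples %||% unique(hits$sample_id)
  hmms <- hmms %||% sort(unique(hits$hmm_id))
  calls <- matrix(0L, nrow = length(samples), ncol = length(hmms),
                  dimnames = list(samples, hmms))
  pos <- hits[hits$bitscore > threshold &
                hits$sample_id %in% samples &
                hits$hmm_id %in% hmms, c("sample_id", "hmm_id")]
  if (nrow(pos)) {
    calls[cbind(match(pos$sample_id, samples), match(pos$hmm_id, hmms))] <- 1L
  }
  new_presence_matrix(calls,
                      rule = list(type = "threshold", threshold = threshold))
}

new_presence_matrix <- function(calls, rule) {
  stopifnot(is.matrix(calls), !is.null(rownames(calls)),
            !is.null(colnames(calls)), all(calls %in% c(0L, 1L)))
  structure(calls, rule = rule, class = c("presence_matrix", class(calls)))
}

#' @export
print.presence_matrix <- function(x, ...) {
  rule <- attr(x, "rule")
  cat(sprintf("presence_matrix: %d samples x %d HMMs (%s rule)\n",
              nrow(x), ncol(x), rule$type %||% "unknown"))
  cat(sprintf("  positive calls: %d of %d\n", sum(x), length(x)))
  invisible(x)
}

#' Annotate presence with a dual-HMM score ratio
#'
#' Some protein families sit inside large, diverse superfamilies, and a
#' single-HMM threshold picks up scattered superfamily artifacts. The ratio
#' rule calls a sample positive only if some transcript scores above
#' `floor` against the target HMM *and* at least `factor` times its best
#' score against a broader reference HMM (e.g. a CbbX-type Rubisco activase
#' HMM against the generic AAA+ family HMM, with `factor = 5`).
#'
#' Scores are compared per transcript, taking each transcript's best
#' (maximum) bitscore per HMM. A transcript with a target hit but no
#' reference hit has its reference score imputed as `floor`, so absent
#' reference evidence never disqualifies a strong target hit.
#'
#' @param hits_target Hit records for the target HMM.
#' @param hits_reference Hit records for the reference HMM.
#' @param factor Required ratio of target to reference bitscore (> 0).
#' @param floor Minimum target bitscore (strict), also the imputed
#'   reference score for transcripts without a reference hit.
#' @param samples Sample ids for the result vector; defaults to samples
#'   seen in `hits_target`.
#' @return Named integer 0/1 vector over `samples`.
#' @export
ratio_call <- function(hits_target, hits_reference, factor = 5, floor = 10,
                       samples = NULL) {
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0) {
    stop_param("factor must be a single positive number")
  }
  samples <- samples %||% unique(hits_target$sample_id)
  out <- setNames(integer(length(samples)), samples)
  if (!nrow(hits_target)) {
    return(out)
  }
  best <- function(h) {
    dplyr::summarise(
      dplyr::group_by(h, .data$sample_id, .data$transcript_id),
      score = max(.data$bitscore), .groups = "drop"
    )
  }
  bt <- best(hits_target)
  br <- best(hits_reference)
  j <- dplyr::left_join(bt, br, by = c("sample_id", "transcript_id"),
                        suffix = c("_target", "_ref"))
  ref <- ifelse(is.na(j$score_ref), floor, j$score_ref)
  hit <- j$score_target > floor & j$score_target >= factor * ref
  pos <- unique(j$sample_id[hit])
  out[intersect(pos, samples)] <- 1L
  out
}

#' Per-clade hit fractions
#'
#' For each HMM and clade, counts the samples called positive and reports
#' the fraction of the clade's transcriptomes with a hit.
#'
#' @param matrix A `presence_matrix`.
#' @param clades Clade map tibble (`sample_id`, `clade`) covering every
#'   matrix sample.
#' @return Tibble with columns `hmm_id`, `clade`, `positives`,
#'   `clade_size`, `fraction`, clades ordered by first appearance in the
#'   clade map.
#' @export
clade_fractions <- function(matrix, clades) {
  unlabeled <- setdiff(rownames(matrix), clades$sample_id)
  if (length(unlabeled)) {
    stop_input("samples missing from the clade map: ",
               paste(unlabeled, collapse = ", "))
  }
  if (ncol(matrix) == 0L || nrow(matrix) == 0L) {
    return(tibble::tibble(hmm_id = character(), clade = character(),
                          positives = integer(), clade_size = integer(),
                          fraction = double()))
  }
  lab <- clades$clade[match(rownames(matrix), clades$sample_id)]
  clade_order <- unique(clades$clade[clades$sample_id %in% rownames(matrix)])
  lab <- factor(lab, levels = clade_order)
  pos <- rowsum(unclass(matrix), lab)          # clade x hmm positive counts
  sizes <- as.integer(table(lab))
  tibble::tibble(
    hmm_id = rep(colnames(matrix), each = length(clade_order)),
    clade = rep(clade_order, times = ncol(matrix)),
    positives = as.integer(pos[cbind(
      rep(seq_along(clade_order), times = ncol(matrix)),
      rep(seq_len(ncol(matrix)), each = length(clade_order)))]),
    clade_size = rep(sizes, times = ncol(matrix)),
    fraction = .data$positives / .data$clade_size
  )
}

#' Write / read a presence matrix as TSV
#'
#' Samples as rows, HMM ids as columns, entries 0/1. The first column is
#' `sample_id`. Round-trips exactly.
#'
#' @param matrix A `presence_matrix` (or plain 0/1 matrix with dimnames).
#' @param path Output path.
#' @param params Optional named parameters recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_presence_matrix <- function(matrix, path, params = list()) {
  df <- tibble::as_tibble(unclass(matrix), rownames = "sample_id")
  write_tsv_with_header(df, path, params)
}

#' @rdname write_presence_matrix
#' @export
read_presence_matrix <- function(path) {
  if (!file.exists(path)) {
    stop_input("presence matrix not found: ", path)
  }
  df <- readr::read_tsv(path, comment = "#", progress = FALSE,
                        col_types = readr::cols(
                          sample_id = readr::col_character(),
                          .default = readr::col_integer()))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$sample_id
  if (!all(m %in% c(0L, 1L))) {
    stop_input("presence matrix ", path, " contains entries other than 0/1")
  }
  new_presence_matrix(m, rule = list(type = "file", path = path))
}
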