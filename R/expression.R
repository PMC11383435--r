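## Message numbers from RNA-seq. Relative RNA-seq alone fixes only the
## per-gene share of transcription; the absolute scale (total transcripts
## produced per cell cycle) is a required, documented parameter.

#' Message numbers from an RNA-seq count table
#'
#' Converts mapped-read counts to message numbers (transcripts per gene
#' per cell cycle): counts are length-normalised to transcript shares
#' (optional, on by default; disable for 3'-counting protocols), shares
#' sum to one, and are scaled by the configured total transcripts per cell
#' cycle, so \code{sum(mu_m) == totalMessages}. Genes whose message number
#' falls below one transcript per cell cycle are flagged as below the
#' one-message-rule threshold.
#'
#' @param counts \code{data.frame} with \code{gene_id}, \code{count} and,
#'   for length normalisation, \code{length_bp}; or a named count vector.
#' @param totalMessages total transcripts produced per cell cycle (the
#'   absolute scale; default 2e4, a bacterial order of magnitude).
#' @param lengthNormalize divide counts by gene length before forming
#'   shares.
#' @return \code{data.frame} with \code{gene_id}, \code{mu_m},
#'   \code{below_one_message}.
#' @examples
#' messageNumberFromCounts(c(a = 10, b = 10), totalMessages = 60,
#'   lengthNormalize = FALSE) # 30 each
#' @export
messageNumberFromCounts <- function(counts, totalMessages = 2e4,
                                    lengthNormalize = TRUE) {
  if (totalMessages <= 0) stop("totalMessages must be positive")
  if (is.numeric(counts)) {
    counts <- data.frame(
      gene_id = names(counts) %||% sprintf("gene_%04d", seq_along(counts)),
      count = as.numeric(counts)
    )
  }
  if (!all(c("gene_id", "count") %in% names(counts))) {
    stop("counts needs columns gene_id and count")
  }
  if (any(counts$count < 0)) stop("counts must be >= 0")
  if (sum(counts$count) <= 0) stop("total count must be positive")
  w <- counts$count
  if (lengthNormalize) {
    if (!"length_bp" %in% names(counts)) {
      stop("length normalisation requested but length_bp is missing")
    }
    if (any(counts$length_bp <= 0)) stop("lengths must be positive")
    w <- w / counts$length_bp
  }
  mu <- totalMessages * w / sum(w)
  data.frame(
    gene_id = counts$gene_id, mu_m = mu,
    below_one_message = mu < 1
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Join classification and expression tables
#'
#' Inner join on \code{gene_id} of a per-gene classification table (from
#' [classifyLibrary()]) and an expression table (from
#' [messageNumberFromCounts()]). Genes missing from either side are
#' reported in the \code{"reconciliation"} attribute; duplicated ids are
#' an error.
#'
#' @param classification \code{data.frame} with \code{gene_id} (+ class
#'   columns).
#' @param expression \code{data.frame} with \code{gene_id}, \code{mu_m}.
#' @return joined \code{data.frame}; attribute \code{"reconciliation"} is a
#'   list with \code{missing_in_expression} and
#'   \code{missing_in_classification}.
#' @export
joinOverabundanceExpression <- function(classification, expression) {
  for (nm in list(
    list(classification, "classification"),
    list(expression, "expression")
  )) {
    d <- table(nm[[1]]$gene_id)
    if (any(d > 1)) {
      stop(
        "duplicated gene_ids in ", nm[[2]], ": ",
        paste(names(d)[d > 1], collapse = ", ")
      )
    }
  }
  joined <- merge(classification, expression, by = "gene_id")
  attr(joined, "reconciliation") <- list(
    missing_in_expression = setdiff(
      classification$gene_id, expression$gene_id
    ),
    missing_in_classification = setdiff(
      expression$gene_id, classification$gene_id
    )
  )
  joined
}
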