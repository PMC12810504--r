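# Drug-target consensus across prediction tools and the drug-disease
# overlap set.

#' Read a drug-target prediction table
#'
#' @param path TSV with header and columns `drug`, `predictor`, `gene`
#' @return data.frame with normalized gene symbols, duplicates dropped
#' @export
load_drug_targets <- function(path) {
  if (!file.exists(path)) np_stop("drug-target table not found: %s", path)
  df <- read.delim(path, header = TRUE, colClasses = "character")
  need <- c("drug", "predictor", "gene")
  if (!all(need %in% names(df))) {
    np_stop("drug-target table must have columns: %s", paste(need, collapse = ", "))
  }
  df$gene <- toupper(trimws(df$gene))
  df <- df[nzchar(df$gene) & nzchar(df$predictor) & nzchar(df$drug), need]
  unique(df)
}

#' Consensus targets of one drug across predictors
#'
#' Keeps genes predicted by at least `min_agreement` of the prediction
#' tools for a single drug — the same k-of-n rule used for disease
#' evidence, applied to e.g. Swiss Target Prediction / SEA / TargetNet
#' output.
#'
#' @param predictions data.frame (`drug`, `predictor`, `gene`) for one drug,
#'   or a named list of per-predictor gene vectors
#' @param min_agreement minimum number of agreeing predictors (default 2)
#' @return sorted character vector of consensus target symbols
#' @export
consensus_targets <- function(predictions, min_agreement = 2L) {
  min_agreement <- as.integer(min_agreement)
  if (is.data.frame(predictions)) {
    if (length(unique(predictions$drug)) > 1L) {
      np_stop("consensus_targets() expects one drug; got: %s",
              paste(unique(predictions$drug), collapse = ", "))
    }
    by_pred <- split(predictions$gene, predictions$predictor)
  } else {
    by_pred <- predictions
  }
  if (length(by_pred) < min_agreement) {
    np_stop("min_agreement (%d) exceeds number of predictors (%d)",
            min_agreement, length(by_pred))
  }
  by_pred <- lapply(by_pred, function(g) unique(toupper(trimws(g))))
  counts <- table(unlist(by_pred))
  sort(names(counts)[counts >= min_agreement])
}

#' Consensus targets for every drug in a prediction table
#'
#' @param predictions data.frame (`drug`, `predictor`, `gene`)
#' @param min_agreement per-drug agreement threshold
#' @return named list drug -> consensus gene vector
#' @export
consensus_by_drug <- function(predictions, min_agreement = 2L) {
  lapply(split(predictions, predictions$drug),
         consensus_targets, min_agreement = min_agreement)
}

#' Overlap between drug consensus targets and a disease gene set
#'
#' Policy `"all_drugs"` intersects the disease set with targets common to
#' every drug (genes regulated by all compounds); `"any_drug"` with the
#' union of per-drug targets.
#'
#' @param consensus named list drug -> consensus gene vector
#' @param disease character vector of disease-associated genes
#' @param policy `"all_drugs"` (default) or `"any_drug"`
#' @return an `overlap_result`: list with `shared` (sorted gene vector),
#'   `per_drug` (disease overlap of each drug), `policy`, `disease_size`
#' @export
disease_overlap <- function(consensus, disease, policy = c("all_drugs", "any_drug")) {
  if (length(consensus) < 1L) np_stop("need at least one drug consensus set")
  if (length(disease) == 0L) np_stop("disease gene set is empty")
  policy <- match.arg(policy)
  disease <- unique(toupper(trimws(disease)))
  consensus <- lapply(consensus, function(g) unique(toupper(trimws(g))))
  pooled <- if (policy == "all_drugs") Reduce(intersect, consensus) else Reduce(union, consensus)
  structure(
    list(shared = sort(intersect(disease, pooled)),
         per_drug = lapply(consensus, function(g) sort(intersect(disease, g))),
         policy = policy,
         disease_size = length(disease)),
    class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> policy=%s shared=%d genes\n", x$policy, length(x$shared)))
  for (d in names(x$per_drug)) {
    cat(sprintf("  %s: %d disease-overlapping targets\n", d, length(x$per_drug[[d]])))
  }
  invisible(x)
}
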