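# Comparison metrics for indirect predictions against the full-data
# evaluation, with parent-status grouping.

#' Accuracy of indirect predictions
#'
#' Pearson correlation between full-evaluation GEBV and indirect GEBV.
#'
#' @param fullGebv,indirectGebv paired numeric vectors (length >= 3).
#' @return numeric(1).
#' @export
accuracy <- function(fullGebv, indirectGebv) {
  stopifnot(length(fullGebv) == length(indirectGebv), length(fullGebv) >= 3)
  if (sd(fullGebv) == 0 || sd(indirectGebv) == 0)
    stop("zero variance; correlation undefined")
  cor(fullGebv, indirectGebv)
}

#' Dispersion of indirect predictions
#'
#' OLS slope of full-evaluation GEBV regressed on indirect GEBV (full is
#' the response); 1 means no over- or under-dispersion.
#'
#' @inheritParams accuracy
#' @return numeric(1) regression slope.
#' @export
dispersion <- function(fullGebv, indirectGebv) {
  stopifnot(length(fullGebv) == length(indirectGebv))
  if (var(indirectGebv) == 0) stop("zero variance of the regressor")
  as.numeric(cov(fullGebv, indirectGebv) / var(indirectGebv))
}

#' Level bias of indirect predictions
#'
#' mean(indirect - full) / sigmaU, in genetic-SD units; sign convention
#' is indirect minus full, so a positive value means the indirect
#' predictions run high.
#'
#' @inheritParams accuracy
#' @param sigmaU genetic standard deviation (> 0).
#' @return numeric(1).
#' @export
levelBias <- function(fullGebv, indirectGebv, sigmaU = 1) {
  stopifnot(sigmaU > 0, length(fullGebv) == length(indirectGebv))
  mean(indirectGebv - fullGebv) / sigmaU
}

#' @importFrom stats cov
NULL

#' Compare indirect predictions with the full evaluation
#'
#' Builds the per-method, per-parent-status-group (GG/NG/NN, plus
#' overall) table of accuracy, dispersion slope and level bias.
#'
#' @param indirect data frame from [predictIndirect()].
#' @param fullGebv named numeric: full-evaluation GEBV by candidate id.
#' @param sigmaU genetic SD used for level bias.
#' @return data frame `method`, `group`, `n`, `accuracy`, `slope`,
#'   `level_bias`.
#' @export
compareIndirect <- function(indirect, fullGebv, sigmaU = 1) {
  rows <- list()
  for (method in unique(indirect$method)) {
    sub <- indirect[indirect$method == method, ]
    full <- fullGebv[sub$candidate]
    if (anyNA(full)) stop("full-evaluation GEBV missing for some candidates")
    groups <- c(list(overall = seq_len(nrow(sub))),
                split(seq_len(nrow(sub)), sub$parent_status))
    for (gname in names(groups)) {
      idx <- groups[[gname]]
      if (length(idx) < 3) next
      rows[[paste(method, gname)]] <- data.frame(
        method = method, group = gname, n = length(idx),
        accuracy = accuracy(full[idx], sub$gebv[idx]),
        slope = dispersion(full[idx], sub$gebv[idx]),
        level_bias = levelBias(full[idx], sub$gebv[idx], sigmaU))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
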