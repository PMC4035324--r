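#' Relative expression by the 2^-ddCt method
#'
#' Livak relative quantification of a target gene against a reference
#' (internal control) gene and a calibrator stage. Replicate Ct values are
#' averaged on the Ct scale, then per stage
#' `dCt = mean Ct(target) - mean Ct(reference)`,
#' `ddCt = dCt(stage) - dCt(calibrator)`, and `RQ = 2^-ddCt`. The calibrator
#' stage gets RQ = 1 exactly. No amplification-efficiency correction is
#' applied.
#'
#' @param table Ct table: data frame with columns `gene_id`, `stage`,
#'   `replicate`, `ct` (cycles, > 0).
#' @param target Target gene id.
#' @param reference Reference (control) gene id, e.g. GAPDH.
#' @param calibrator Calibrator stage label.
#' @return Data frame `stage`, `delta_ct`, `delta_delta_ct`, `rq`, in the
#'   order the stages appear in the table.
#' @export
relative_expression <- function(table, target, reference, calibrator) {
  need <- c("gene_id", "stage", "ct")
  if (!all(need %in% names(table)))
    stop("Ct table needs columns gene_id, stage, ct", call. = FALSE)
  if (any(table$ct <= 0)) stop("Ct values must be > 0", call. = FALSE)
  tgt <- table[table$gene_id == target, , drop = FALSE]
  ref <- table[table$gene_id == reference, , drop = FALSE]
  if (nrow(tgt) == 0) stop("target gene not in table: ", target, call. = FALSE)
  stages <- unique(tgt$stage)
  if (!calibrator %in% stages)
    stop("calibrator stage not measured for the target: ", calibrator,
         call. = FALSE)
  missing_ref <- setdiff(stages, unique(ref$stage))
  if (length(missing_ref))
    stop("reference gene not measured in stage ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  mean_tgt <- tapply(tgt$ct, tgt$stage, mean)
  mean_ref <- tapply(ref$ct, ref$stage, mean)
  dct <- mean_tgt[stages] - mean_ref[stages]
  ddct <- dct - dct[[calibrator]]
  data.frame(stage = stages,
             delta_ct = as.numeric(dct),
             delta_delta_ct = as.numeric(ddct),
             rq = 2^(-as.numeric(ddct)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a Ct table from TSV
#'
#' @param path TSV with header columns `gene_id`, `stage`, `replicate`, `ct`.
#' @return Data frame.
#' @export
read_ct_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
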