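# Customized RT2 array analysis: housekeeping-gene normalization,
# 2^-ddCt fold changes relative to the young group, Ct floor at 35,
# replicate averaging, +-1.5 fold-change regulation calls, log2 transform.

#' Construct a gene x sample Ct table
#'
#' @param ct numeric matrix, genes in rows (rownames), samples in columns
#'   (colnames); cycles, in (0, 45] or `NA` for undetermined.
#' @param sample_meta data.frame with columns `sample`, `group`
#'   (`"young"`/`"old"`) and `replicate` (replicate-experiment id pairing one
#'   young with one old pooled sample).
#' @param hkgs housekeeping genes used for normalization; all five must be
#'   present in `ct` (default Gusb, Actb, Gapdh, B2m, Hsp90ab1).
#' @param ct_floor lower limit of detection, cycles (default 35).
#' @return object of class `ct_table`.
#' @export
ct_table <- function(ct, sample_meta,
                     hkgs = c("Gusb", "Actb", "Gapdh", "B2m", "Hsp90ab1"),
                     ct_floor = 35) {
  stopifnot(is.matrix(ct), !is.null(rownames(ct)), !is.null(colnames(ct)))
  if (!all(hkgs %in% rownames(ct))) {
    stop("all housekeeping genes must be present in the Ct matrix", call. = FALSE)
  }
  stopifnot(is.data.frame(sample_meta),
            all(c("sample", "group", "replicate") %in% names(sample_meta)))
  if (!setequal(sample_meta$sample, colnames(ct))) {
    stop("sample_meta must cover exactly the Ct table's samples", call. = FALSE)
  }
  if (!all(sample_meta$group %in% c("young", "old"))) {
    stop("groups must be 'young' or 'old'", call. = FALSE)
  }
  bad <- !is.na(ct) & (ct <= 0 | ct > 45)
  if (any(bad)) stop("Ct values must lie in (0, 45] or be NA", call. = FALSE)
  sample_meta <- sample_meta[match(colnames(ct), sample_meta$sample), ]
  structure(list(ct = ct, sample_meta = sample_meta, hkgs = hkgs,
                 ct_floor = ct_floor),
            class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("ct_table: %d genes x %d samples (%d young, %d old), floor Ct=%g\n",
              nrow(x$ct), ncol(x$ct), sum(x$sample_meta$group == "young"),
              sum(x$sample_meta$group == "old"), x$ct_floor))
  invisible(x)
}

#' Apply the lower limit of detection (Ct floor)
#'
#' Every Ct above the floor, and every missing/undetermined value, is replaced
#' by the floor (default 35) to avoid over-calculation of fold changes for
#' genes outside assay sensitivity. Idempotent.
#'
#' @param x a [ct_table()].
#' @return the floored [ct_table()].
#' @export
apply_floor <- function(x) {
  stopifnot(inherits(x, "ct_table"))
  ct <- x$ct
  ct[is.na(ct) | ct > x$ct_floor] <- x$ct_floor
  x$ct <- ct
  x$floored <- TRUE
  x
}

#' 2^-ddCt fold changes of old relative to young
#'
#' For each sample, `dCt(gene) = Ct(gene) - mean(Ct of the housekeeping
#' genes)`. For each replicate experiment, `ddCt(gene) = mean dCt(old) -
#' mean dCt(young)` within that replicate and `FC = 2^-ddCt`. The per-gene
#' average fold change is the arithmetic mean across replicates; calls are
#' `up` if avg FC > `up_fc`, `down` if avg FC < 1/`up_fc`, else `unchanged`.
#' The Ct floor is applied first if it has not been already.
#'
#' @param x a [ct_table()].
#' @param up_fc regulation-call threshold on the decimal fold change
#'   (default 1.5; down threshold is its reciprocal).
#' @return object of class `fold_change_result`: data.frame `table` with
#'   columns `gene`, `fc_rep<i>`..., `avg_fc`, `log2_fc`, `fold_regulation`
#'   (signed display form: FC if >= 1, else -1/FC), `call`; plus `up_fc` and
#'   `warnings` (genes skipped).
#' @export
ddct_fold_change <- function(x, up_fc = 1.5) {
  stopifnot(inherits(x, "ct_table"))
  if (!isTRUE(x$floored)) x <- apply_floor(x)
  meta <- x$sample_meta
  if (!all(c("young", "old") %in% meta$group)) {
    stop("both groups must be present", call. = FALSE)
  }
  hk <- colMeans(x$ct[x$hkgs, , drop = FALSE])
  dct <- sweep(x$ct, 2L, hk)              # gene x sample delta-Ct
  reps <- sort(unique(meta$replicate))
  genes <- setdiff(rownames(x$ct), x$hkgs)
  fc <- matrix(NA_real_, length(genes), length(reps),
               dimnames = list(genes, paste0("fc_rep", reps)))
  for (j in seq_along(reps)) {
    yi <- meta$sample[meta$group == "young" & meta$replicate == reps[j]]
    oi <- meta$sample[meta$group == "old" & meta$replicate == reps[j]]
    if (!length(yi) || !length(oi)) next
    ddct <- rowMeans(dct[genes, oi, drop = FALSE]) -
      rowMeans(dct[genes, yi, drop = FALSE])
    fc[, j] <- 2^(-ddct)
  }
  skipped <- genes[apply(fc, 1L, function(r) all(is.na(r)))]
  avg <- rowMeans(fc, na.rm = TRUE)
  call <- ifelse(avg > up_fc, "up", ifelse(avg < 1 / up_fc, "down", "unchanged"))
  tab <- data.frame(gene = genes, fc, avg_fc = avg, log2_fc = log2(avg),
                    fold_regulation = ifelse(avg >= 1, avg, -1 / avg),
                    call = call, row.names = NULL, check.names = FALSE)
  tab <- tab[!tab$gene %in% skipped, , drop = FALSE]
  structure(list(table = tab, up_fc = up_fc,
                 warnings = if (length(skipped))
                   paste("skipped (missing in a group):",
                         paste(skipped, collapse = ", ")) else character(0)),
            class = "fold_change_result")
}

#' @export
print.fold_change_result <- function(x, ...) {
  cat(sprintf("fold_change_result: %d genes, thresholds FC > %.2f (up) / < %.3f (down)\n",
              nrow(x$table), x$up_fc, 1 / x$up_fc))
  n <- table(factor(x$table$call, c("up", "down", "unchanged")))
  cat(sprintf("  up: %d, down: %d, unchanged: %d\n", n[["up"]], n[["down"]],
              n[["unchanged"]]))
  if (length(x$warnings)) cat(" ", x$warnings, "\n")
  invisible(x)
}

#' Log2-transformed average fold changes
#'
#' Log2 of the per-gene average fold change, for plotting relative to zero;
#' the up-regulation threshold FC = 1.5 maps to log2(1.5) = 0.585 (3 dp) and
#' the down threshold to -0.585.
#'
#' @param fc a `fold_change_result`.
#' @return named numeric vector of log2 fold changes.
#' @export
log2_transform <- function(fc) {
  stopifnot(inherits(fc, "fold_change_result"))
  stats::setNames(log2(fc$table$avg_fc), fc$table$gene)
}

#' Read a Ct table from CSV
#'
#' @param ct_path long-format CSV with columns `gene`, `sample`, `ct`.
#' @param sample_sheet_path CSV with columns `sample`, `group`, `replicate`.
#' @param ... passed to [ct_table()].
#' @return a [ct_table()].
#' @export
read_ct_csv <- function(ct_path, sample_sheet_path, ...) {
  d <- utils::read.csv(ct_path)
  stopifnot(all(c("gene", "sample", "ct") %in% names(d)))
  m <- stats::xtabs(ct ~ gene + sample, data = d)
  m <- matrix(as.numeric(m), nrow = nrow(m),
              dimnames = list(rownames(m), colnames(m)))
  m[m == 0] <- NA_real_   # xtabs encodes absent combinations as 0
  ct_table(m, utils::read.csv(sample_sheet_path), ...)
}

#' Write a fold-change table to CSV
#'
#' @param fc a `fold_change_result`.
#' @param path output CSV path.
#' @export
write_fold_change_csv <- function(fc, path) {
  utils::write.csv(fc$table, path, row.names = FALSE)
  invisible(path)
}
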