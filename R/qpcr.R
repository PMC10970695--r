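#' Average technical qPCR replicates
#'
#' Collapses technical replicates to one Ct per biological replicate by
#' arithmetic mean. Technical replicates spreading more than
#' `flag_delta` cycles are flagged (a common plate-QC convention) but
#' not removed.
#'
#' @param measurements tidy data.frame with `sample`, `tissue`, `gene`,
#'   `bio_rep`, `tech_rep`, `ct`
#' @param flag_delta flag threshold on the within-group Ct range
#'   (cycles)
#' @return data.frame with `sample`, `tissue`, `gene`, `bio_rep`, `ct`,
#'   `divergent`
#' @export
average_technical <- function(measurements, flag_delta = 1) {
  stopifnot(all(c("sample", "tissue", "gene", "bio_rep", "ct") %in%
                  names(measurements)))
  if (any(measurements$ct <= 0, na.rm = TRUE))
    stop("Ct values must be positive")
  key <- c("sample", "tissue", "gene", "bio_rep")
  mean_ct <- aggregate(ct ~ sample + tissue + gene + bio_rep,
                       measurements, mean)
  range_ct <- aggregate(ct ~ sample + tissue + gene + bio_rep,
                        measurements, function(v) diff(range(v)))
  out <- merge(mean_ct, range_ct, by = key, suffixes = c("", "_range"))
  out$divergent <- out$ct_range > flag_delta
  out$ct_range <- NULL
  out[order(out$gene, out$tissue, out$sample, out$bio_rep), ]
}

#' Relative expression by the 2^-ddCt method
#'
#' Normalises each target gene to the reference gene within each
#' biological replicate (dCt = Ct_target - Ct_reference), then to the
#' calibrator sample within each tissue (ddCt = mean dCt(sample) -
#' mean dCt(calibrator)), and reports RQ = 2^-ddCt. Between-sample
#' significance is a two-sided Welch t-test on the per-replicate dCt
#' values ([expression_test()]). Amplification efficiency is the
#' method's assumed perfect doubling.
#'
#' @param bio_ct per-biological-replicate Ct table from
#'   [average_technical()]
#' @param reference_gene internal reference (housekeeping) gene name
#' @param calibrator sample id used as the expression baseline within
#'   each tissue
#' @return data.frame with `gene`, `tissue`, `sample`, `n_rep`,
#'   `mean_dct`, `ddct`, `rq`, `p_value`, `signif`
#' @export
delta_delta_ct <- function(bio_ct, reference_gene = "Actin",
                           calibrator = "P2") {
  stopifnot(all(c("sample", "tissue", "gene", "bio_rep", "ct") %in%
                  names(bio_ct)))
  ref <- bio_ct[bio_ct$gene == reference_gene, ]
  if (nrow(ref) == 0L)
    stop("reference gene '", reference_gene, "' not found")
  tgt <- bio_ct[bio_ct$gene != reference_gene, ]
  key <- paste(tgt$sample, tgt$tissue, tgt$bio_rep)
  rkey <- paste(ref$sample, ref$tissue, ref$bio_rep)
  ridx <- match(key, rkey)
  if (any(is.na(ridx))) {
    bad <- unique(paste0(tgt$sample[is.na(ridx)], "/",
                         tgt$tissue[is.na(ridx)]))
    warning("sample(s) without reference-gene Ct rejected: ",
            paste(bad, collapse = ", "))
    tgt <- tgt[!is.na(ridx), ]
    ridx <- ridx[!is.na(ridx)]
  }
  tgt$dct <- tgt$ct - ref$ct[ridx]
  out <- list(); k <- 0L
  for (gene in unique(tgt$gene)) {
    for (tis in unique(tgt$tissue[tgt$gene == gene])) {
      sub <- tgt[tgt$gene == gene & tgt$tissue == tis, ]
      cal <- sub$dct[sub$sample == calibrator]
      if (length(cal) == 0L) {
        warning("no calibrator '", calibrator, "' for ", gene, "/", tis)
        next
      }
      for (smp in unique(sub$sample)) {
        d <- sub$dct[sub$sample == smp]
        ddct <- mean(d) - mean(cal)
        tst <- if (smp == calibrator)
          list(p_value = 1, flag = "")
        else expression_test(d, cal)
        k <- k + 1L
        out[[k]] <- data.frame(
          gene = gene, tissue = tis, sample = smp, n_rep = length(d),
          mean_dct = mean(d), ddct = ddct, rq = 2^(-ddct),
          p_value = tst$p_value, signif = tst$flag,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Welch t-test on dCt values between two sample groups
#'
#' Two-sided Welch (unequal-variance) t-test on the biological
#' replicates' dCt values; the standard test for 2^-ddCt designs.
#' Flags `"*"` at p < 0.05 and `"**"` at p < 0.001. Two groups with
#' zero variance and equal means give p = 1 (no evidence either way).
#'
#' @param delta_ct_a,delta_ct_b numeric dCt vectors (>= 2 replicates
#'   each)
#' @return list with `p_value`, `t`, `flag`
#' @export
expression_test <- function(delta_ct_a, delta_ct_b) {
  if (length(delta_ct_a) < 2L || length(delta_ct_b) < 2L)
    stop("need at least 2 biological replicates per group")
  va <- var(delta_ct_a); vb <- var(delta_ct_b)
  if (va == 0 && vb == 0) {
    p <- if (mean(delta_ct_a) == mean(delta_ct_b)) 1 else 0
    tt <- if (p == 1) 0 else Inf
  } else {
    ht <- t.test(delta_ct_a, delta_ct_b)
    p <- ht$p.value
    tt <- unname(ht$statistic)
  }
  flag <- if (p < 0.001) "**" else if (p < 0.05) "*" else ""
  list(p_value = p, t = tt, flag = flag)
}

#' Full qPCR relative-expression analysis from raw technical replicates
#'
#' Convenience wrapper: [average_technical()] then [delta_delta_ct()].
#'
#' @inheritParams average_technical
#' @inheritParams delta_delta_ct
#' @return the [delta_delta_ct()] report
#' @export
qpcr_report <- function(measurements, reference_gene = "Actin",
                        calibrator = "P2", flag_delta = 1) {
  delta_delta_ct(average_technical(measurements, flag_delta),
                 reference_gene, calibrator)
}
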