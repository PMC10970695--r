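#' Additive/dominance design encoding of F2 bin genotypes
#'
#' Codes each bin marker as an additive covariate `x` (A = 1, H = 0,
#' B = -1) and a dominance covariate `z` (H = 1, A/B = 0). Missing
#' calls are imputed by the marker mean; markers with zero additive
#' variance (monomorphic, or all heterozygous) are dropped with a
#' warning since they carry no additive information.
#'
#' @param bg a [genotype_bins()] result (or an integer genotype matrix,
#'   bins x lines, codes 1/2/3)
#' @return list with matrices `x`, `z` (lines x markers), `markers`
#'   (kept bin ids), `keep` (row indices into the bin table), `dropped`
#' @export
encode_f2_covariates <- function(bg) {
  geno <- if (inherits(bg, "bin_geno")) bg$geno else bg
  ids <- rownames(geno)
  if (is.null(ids)) ids <- sprintf("m%04d", seq_len(nrow(geno)))
  x <- t(2L - geno)          # A=1, H=0, B=-1
  z <- t(geno == 2L) * 1
  imp <- function(m) {
    mu <- colMeans(m, na.rm = TRUE)
    nas <- which(is.na(m), arr.ind = TRUE)
    if (nrow(nas)) m[nas] <- mu[nas[, 2]]
    m
  }
  x <- imp(x); z <- imp(z)
  vx <- apply(x, 2, var)
  keep <- which(!is.na(vx) & vx > 0)
  if (length(keep) < ncol(x))
    warning(ncol(x) - length(keep),
            " marker(s) without additive variance dropped")
  list(x = x[, keep, drop = FALSE], z = z[, keep, drop = FALSE],
       markers = ids[keep], keep = keep,
       dropped = ids[setdiff(seq_along(ids), keep)])
}

# RSS decrease from adding each candidate (x, z) marker block to the
# model spanned by qr_cur; vectorised over candidates.
block_rss_drop <- function(qr_cur, e, x, z) {
  rx <- qr.resid(qr_cur, x)
  rz <- qr.resid(qr_cur, z)
  ex <- as.numeric(crossprod(e, rx))
  ez <- as.numeric(crossprod(e, rz))
  gxx <- colSums(rx^2)
  gzz <- colSums(rz^2)
  gxz <- colSums(rx * rz)
  det <- gxx * gzz - gxz^2
  scale <- pmax(gxx * gzz, 1e-300)
  full <- det / scale > 1e-10          # block has rank 2
  drop2 <- (ex^2 * gzz - 2 * ex * ez * gxz + ez^2 * gxx) / det
  drop1 <- ifelse(gxx > 1e-12, ex^2 / gxx,
                  ifelse(gzz > 1e-12, ez^2 / gzz, 0))
  dr <- ifelse(full, drop2, drop1)
  df <- ifelse(full, 2L, ifelse(gxx > 1e-12 | gzz > 1e-12, 1L, 0L))
  list(drop = pmax(dr, 0), df = df)
}

#' Stepwise cofactor selection (ICIM phase 1)
#'
#' Forward-backward stepwise linear regression of the phenotype on the
#' additive/dominance marker pairs, with entry and exit decided by
#' partial-F p-values. This is the marker-selection phase of inclusive
#' composite interval mapping; the selected markers later serve as
#' background cofactors for the genome scan.
#'
#' @param design an [encode_f2_covariates()] result
#' @param phenotype numeric phenotype vector (a 0/1 trait is treated as
#'   quantitative)
#' @param p_in partial-F p-value below which a marker enters
#' @param p_out p-value above which a selected marker is dropped
#' @param max_cofactors cap on the number of selected markers
#' @return list with `selected` (column indices into the design),
#'   `markers` (their ids), `coef` (named coefficients of the final
#'   model) and `fit` (the final `lm`)
#' @export
select_cofactors_stepwise <- function(design, phenotype, p_in = 0.001,
                                      p_out = 0.002,
                                      max_cofactors = NULL) {
  y <- phenotype
  n <- length(y)
  stopifnot(nrow(design$x) == n)
  if (is.null(max_cofactors)) max_cofactors <- max(1L, floor(n / 5))
  m <- ncol(design$x)
  S <- integer(0)
  mm <- function(S) {
    if (length(S) == 0L) matrix(1, n, 1)
    else cbind(1, design$x[, S, drop = FALSE], design$z[, S, drop = FALSE])
  }
  seen <- character(0)   # visited model states: guards against cycling
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 200L) break
    key <- paste(S, collapse = ",")
    if (key %in% seen) break
    seen <- c(seen, key)
    changed <- FALSE
    # forward
    if (length(S) < max_cofactors) {
      X <- mm(S)
      qx <- qr(X)
      e <- qr.resid(qx, y)
      rss <- sum(e^2)
      cand <- setdiff(seq_len(m), S)
      if (length(cand) && rss > 1e-12) {
        br <- block_rss_drop(qx, e, design$x[, cand, drop = FALSE],
                             design$z[, cand, drop = FALSE])
        df2 <- n - qx$rank - br$df
        f <- (br$drop / pmax(br$df, 1)) / ((rss - br$drop) / pmax(df2, 1))
        p <- ifelse(br$df > 0 & df2 > 0 & rss - br$drop > 1e-12,
                    pf(f, br$df, df2, lower.tail = FALSE),
                    ifelse(br$drop > 1e-12, 0, 1))
        best <- which.min(p)   # ties broken by lowest index
        if (p[best] < p_in) {
          S <- sort(c(S, cand[best]))
          changed <- TRUE
        }
      }
    }
    # backward
    if (length(S) > 0L) {
      X <- mm(S)
      rss_full <- sum(qr.resid(qr(X), y)^2)
      k_full <- qr(X)$rank
      pdrop <- vapply(seq_along(S), function(i) {
        Xr <- mm(S[-i])
        rss_r <- sum(qr.resid(qr(Xr), y)^2)
        df1 <- k_full - qr(Xr)$rank
        df2 <- n - k_full
        if (df1 <= 0 || df2 <= 0) return(1)
        f <- ((rss_r - rss_full) / df1) / (rss_full / df2)
        pf(f, df1, df2, lower.tail = FALSE)
      }, 0)
      worst <- which.max(pdrop)
      if (pdrop[worst] > p_out) {
        S <- S[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  X <- mm(S)
  fit <- if (length(S)) {
    colnames(X) <- c("(Intercept)", paste0("x_", design$markers[S]),
                     paste0("z_", design$markers[S]))
    lm.fit(X, y)
  } else lm.fit(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")), y)
  list(selected = S, markers = design$markers[S],
       coef = coef_safe(fit), fit = fit)
}

coef_safe <- function(fit) {
  b <- fit$coefficients
  b[is.na(b)] <- 0
  b
}

# QTL genotype priors for every line at one scan position.
# gL, gR: flanking genotype codes (1/2/3, NA); r1 = rf(left, pos),
# r2 = rf(pos, right). Returns an n x 3 matrix; rows of zeros flag
# lines with neither flank observed (skipped by the scan).
qtl_genotype_priors <- function(gL, gR, r1, r2) {
  r1 <- min(max(r1, 1e-9), 0.5 - 1e-9)
  r2 <- min(max(r2, 1e-9), 0.5 - 1e-9)
  # per-gamete P(Q = P1 allele | flank alleles)
  pq <- function(l, r) {   # l, r in {1 (P1), 2 (P2)}
    t1 <- ifelse(l == 1, 1 - r1, r1)        # P(Q = 1 | L = l)
    t2 <- ifelse(r == 1, 1 - r2, r2)        # P(R = r | Q = 1)
    u1 <- ifelse(l == 1, r1, 1 - r1)
    u2 <- ifelse(r == 1, r2, 1 - r2)
    t1 * t2 / (t1 * t2 + u1 * u2)
  }
  conv <- function(p, q)  # dosage distribution of two Bernoulli gametes
    c(p * q, p * (1 - q) + q * (1 - p), (1 - p) * (1 - q))
  r12 <- r1 * (1 - r2) + (1 - r1) * r2
  wc <- (1 - r12)^2 / ((1 - r12)^2 + r12^2)   # P(cis | double het)
  lookup <- matrix(0, 16, 3)
  key <- function(a, b) (a - 1) * 4 + b       # a, b in 1..3, 4 = missing
  lookup[key(1, 1), ] <- conv(pq(1, 1), pq(1, 1))
  lookup[key(1, 2), ] <- conv(pq(1, 1), pq(1, 2))
  lookup[key(1, 3), ] <- conv(pq(1, 2), pq(1, 2))
  lookup[key(2, 1), ] <- conv(pq(1, 1), pq(2, 1))
  lookup[key(2, 2), ] <- wc * conv(pq(1, 1), pq(2, 2)) +
    (1 - wc) * conv(pq(1, 2), pq(2, 1))
  lookup[key(2, 3), ] <- conv(pq(1, 2), pq(2, 2))
  lookup[key(3, 1), ] <- conv(pq(2, 1), pq(2, 1))
  lookup[key(3, 2), ] <- conv(pq(2, 1), pq(2, 2))
  lookup[key(3, 3), ] <- conv(pq(2, 2), pq(2, 2))
  pL <- function(l) ifelse(l == 1, 1 - r1, r1)   # single-flank left
  pR <- function(r) ifelse(r == 1, 1 - r2, r2)   # single-flank right
  lookup[key(1, 4), ] <- conv(pL(1), pL(1))
  lookup[key(2, 4), ] <- conv(pL(1), pL(2))
  lookup[key(3, 4), ] <- conv(pL(2), pL(2))
  lookup[key(4, 1), ] <- conv(pR(1), pR(1))
  lookup[key(4, 2), ] <- conv(pR(1), pR(2))
  lookup[key(4, 3), ] <- conv(pR(2), pR(2))
  a <- ifelse(is.na(gL), 4L, gL)
  b <- ifelse(is.na(gR), 4L, gR)
  lookup[key(a, b), , drop = FALSE]
}

#' Genome scan by inclusive composite interval mapping
#'
#' Walks each linkage group in `step_cM` steps. At every position the
#' phenotype is adjusted by the selected background cofactors EXCLUDING
#' any cofactor that is a flanking marker of the tested interval; the
#' QTL genotype distribution of each line is derived from its flanking
#' bin genotypes and the interval recombination fractions, and a
#' three-component normal mixture is fitted by EM. The LOD compares the
#' mixture to a single-normal null on the same lines.
#'
#' @param map a [build_genetic_map()] result
#' @param design an [encode_f2_covariates()] result aligned to the map's
#'   bins
#' @param phenotype numeric phenotype vector
#' @param cofactors a [select_cofactors_stepwise()] result (or `NULL`
#'   for plain interval mapping)
#' @param step_cM scan step in cM (marker positions are always tested)
#' @param method `"hk"` (default): Haley-Knott regression on the
#'   prior-expected additive/dominance scores, the sound choice for a
#'   0/1 trait (the full-mixture likelihood is unbounded for binary
#'   phenotypes); `"em"`: three-component normal-mixture EM, for
#'   continuous phenotypes. Both give the plain regression LOD at
#'   fully informative marker positions.
#' @return an object of class `qtl_profile`: data.frame with `lg`,
#'   `chrom`, `cM`, `pos_bp`, `lod`, `a`, `d`, `pve`, `n`
#' @export
scan_icim <- function(map, design, phenotype, cofactors = NULL,
                      step_cM = 1.0, method = c("hk", "em")) {
  pre <- scan_precompute(map, design, step_cM)
  scan_run(pre, design, phenotype, cofactors, method = method)
}

#' Precompute the scan grid and QTL genotype priors
#'
#' The per-position genotype prior matrices depend only on the map and
#' the marker genotypes, not on the phenotype, so they can be computed
#' once and reused across permutations. Returned by this function and
#' accepted by [permutation_threshold()].
#'
#' @inheritParams scan_icim
#' @return an opaque list consumed by the scanning functions
#' @export
scan_precompute <- function(map, design, step_cM = 1.0) {
  stopifnot(inherits(map, "genetic_map"))
  tab <- map$table
  n <- nrow(design$x)
  full_idx <- match(tab$bin, design$markers)
  geno_of <- function(row_idx) {
    j <- full_idx[row_idx]
    if (is.na(j)) return(rep(NA_integer_, n))
    x <- design$x[, j]
    g <- rep(NA_integer_, n)
    g[x == 1] <- 1L; g[x == 0 & design$z[, j] == 1] <- 2L; g[x == -1] <- 3L
    # imputed values are non-integers; they stay NA (missing)
    g
  }
  lgs <- list()
  for (lg in unique(tab$lg)) {
    rows <- which(tab$lg == lg)
    cm <- tab$cM[rows]
    mids <- (tab$start[rows] + tab$end[rows]) / 2
    mrk_geno <- lapply(rows, geno_of)
    m <- length(rows)
    if (m == 1L) {
      P <- qtl_genotype_priors(mrk_geno[[1]], rep(NA_integer_, n),
                               1e-9, 0.25)
      lgs[[lg]] <- list(P = P, cM = cm[1], pos_bp = mids[1],
                        interval = 1L, chrom = tab$chrom[rows[1]],
                        flanks = list(full_idx[rows[1]]))
      next
    }
    Pl <- list(); cms <- list(); bps <- list(); iv <- list()
    flanks <- vector("list", m - 1L)
    for (k in seq_len(m - 1L)) {
      lo <- cm[k]; hi <- cm[k + 1]
      # grid over [lo, hi): the right marker opens the next interval,
      # except at the end of the linkage group where it is included
      pts <- seq(lo, hi, by = step_cM)
      pts <- pts[pts < hi - 1e-9]
      if (length(pts) == 0L) pts <- lo
      if (k == m - 1L) pts <- unique(c(pts, hi))
      dlo <- pts - lo
      dhi <- pmax(hi - pts, 0)
      r1 <- inverse_map_function(dlo, map$kind)
      r2 <- inverse_map_function(dhi, map$kind)
      P <- matrix(0, n, 3L * length(pts))
      for (pi in seq_along(pts))
        P[, (3 * pi - 2):(3 * pi)] <-
          qtl_genotype_priors(mrk_geno[[k]], mrk_geno[[k + 1L]],
                              r1[pi], r2[pi])
      Pl[[k]] <- P
      cms[[k]] <- pts
      bps[[k]] <- mids[k] + (mids[k + 1L] - mids[k]) *
        (if (hi > lo) dlo / (hi - lo) else rep(0, length(pts)))
      iv[[k]] <- rep(k, length(pts))
      fl <- full_idx[rows[c(k, k + 1L)]]
      flanks[[k]] <- fl[!is.na(fl)]
    }
    lgs[[lg]] <- list(P = do.call(cbind, Pl), cM = unlist(cms),
                      pos_bp = unlist(bps), interval = unlist(iv),
                      chrom = tab$chrom[rows[1]], flanks = flanks)
  }
  structure(list(lgs = lgs, step_cM = step_cM, kind = map$kind, n = n),
            class = "icim_scan_pre")
}

# Execute the ICIM scan for one phenotype, reusing precomputed priors.
scan_run <- function(pre, design, phenotype, cofactors = NULL,
                     method = c("hk", "em")) {
  stopifnot(inherits(pre, "icim_scan_pre"))
  method <- match.arg(method)
  kernel <- if (method == "hk") scan_hk_cpp else scan_em_cpp
  coefs <- if (!is.null(cofactors)) cofactors$coef else NULL
  sel <- if (!is.null(cofactors)) cofactors$selected else integer(0)
  adjust <- function(excl) {
    if (length(sel) == 0L) return(phenotype)
    yy <- phenotype
    for (j in setdiff(sel, excl)) {
      bx <- coefs[paste0("x_", design$markers[j])]
      bz <- coefs[paste0("z_", design$markers[j])]
      if (!is.na(bx)) yy <- yy - design$x[, j] * bx
      if (!is.na(bz)) yy <- yy - design$z[, j] * bz
    }
    yy
  }
  y_base <- adjust(integer(0))
  out <- list()
  for (lg in names(pre$lgs)) {
    L <- pre$lgs[[lg]]
    res <- kernel(L$P, y_base)
    if (length(sel)) {
      # intervals flanked by a selected cofactor need their own
      # adjusted phenotype (the flanks are excluded from the cofactors)
      redo <- which(vapply(L$flanks, function(f) any(f %in% sel), TRUE))
      for (k in redo) {
        cols_pos <- which(L$interval == k)
        pc <- as.vector(rbind(3 * cols_pos - 2, 3 * cols_pos - 1,
                              3 * cols_pos))
        y_adj <- adjust(intersect(L$flanks[[k]], sel))
        res[cols_pos, ] <- kernel(L$P[, pc, drop = FALSE], y_adj)
      }
    }
    out[[lg]] <- data.frame(
      lg = lg, chrom = L$chrom, cM = L$cM, pos_bp = L$pos_bp,
      lod = res[, "lod"],
      a = (res[, "muA"] - res[, "muB"]) / 2,
      d = res[, "muH"] - (res[, "muA"] + res[, "muB"]) / 2,
      pve = 100 * (1 - res[, "sigma2"] / res[, "sigma2_null"]),
      n = res[, "n"], stringsAsFactors = FALSE)
  }
  prof <- do.call(rbind, out)
  rownames(prof) <- NULL
  structure(prof, class = c("qtl_profile", "data.frame"),
            step_cM = pre$step_cM, kind = pre$kind)
}

#' Genome-wide LOD significance threshold by permutation
#'
#' Shuffles the phenotype across lines, repeats the full ICIM procedure
#' (cofactor selection and scan) and records the genome-wide maximum
#' LOD; the threshold is the empirical `1 - alpha` quantile taken as
#' the next-higher order statistic (conservative).
#'
#' @param map,design as in [scan_icim()]
#' @param phenotype observed phenotype vector
#' @param n_perm number of permutations
#' @param alpha genome-wide type-I error rate
#' @param seed RNG seed for the permutation stream
#' @param step_cM scan step
#' @param p_in,p_out stepwise thresholds used within each permutation
#' @param pre optional [scan_precompute()] result (computed if missing)
#' @param method scan method, as in [scan_icim()]
#' @return the LOD threshold; attribute `"max_lods"` holds the full
#'   null distribution
#' @export
permutation_threshold <- function(map, design, phenotype, n_perm = 3000L,
                                  alpha = 0.01, seed = 1L, step_cM = 1.0,
                                  p_in = 0.001, p_out = 0.002,
                                  pre = NULL, method = c("hk", "em")) {
  if (n_perm < 100L) stop("n_perm must be at least 100")
  if (is.null(pre)) pre <- scan_precompute(map, design, step_cM)
  method <- match.arg(method)
  set.seed(substream_seed(seed, "permutation"))
  maxlod <- vapply(seq_len(n_perm), function(i) {
    yp <- sample(phenotype)
    cof <- select_cofactors_stepwise(design, yp, p_in = p_in, p_out = p_out)
    prof <- scan_run(pre, design, yp, cof, method = method)
    max(prof$lod, na.rm = TRUE)
  }, 0)
  s <- sort(maxlod)
  # next-higher order statistic of the empirical 1 - alpha quantile
  idx <- min(n_perm, ceiling((n_perm - 1) * (1 - alpha)) + 1L)
  structure(s[idx], max_lods = maxlod, alpha = alpha, n_perm = n_perm)
}

#' LOD-drop support interval around the scan peak
#'
#' Finds the global LOD peak (ties broken leftmost) and returns the
#' maximal contiguous region of its linkage group whose LOD stays
#' within `drop` of the peak, in both genetic and physical coordinates.
#'
#' @param profile a [scan_icim()] result
#' @param drop LOD units to descend from the peak (default 3)
#' @return list with `peak` (the peak row), `lg`, `cM_lo`, `cM_hi`,
#'   `bp_lo`, `bp_hi`, `flat` (TRUE if the whole group is within the
#'   drop, flagged)
#' @export
support_interval <- function(profile, drop = 3.0) {
  stopifnot(inherits(profile, "qtl_profile"))
  pk <- which.max(profile$lod)           # which.max is leftmost on ties
  lg <- profile$lg[pk]
  rows <- which(profile$lg == lg)
  lods <- profile$lod[rows]
  peak_in <- match(pk, rows)
  ok <- !is.na(lods) & lods >= profile$lod[pk] - drop
  lo <- peak_in
  while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
  hi <- peak_in
  while (hi < length(rows) && ok[hi + 1L]) hi <- hi + 1L
  flat <- all(ok)
  if (flat) { lo <- 1L; hi <- length(rows) }
  list(peak = profile[pk, ], lg = lg,
       cM_lo = profile$cM[rows[lo]], cM_hi = profile$cM[rows[hi]],
       bp_lo = profile$pos_bp[rows[lo]], bp_hi = profile$pos_bp[rows[hi]],
       flat = flat)
}

#' Additive/dominance effects and explained variance at a marker
#'
#' From the phenotype means of the three genotype classes at a marker:
#' additive effect `a` = (mean(A) - mean(B)) / 2, dominance effect
#' `d` = mean(H) - (mean(A) + mean(B)) / 2, and the percentage of
#' phenotypic variance explained, 100 (1 - RSS_genotype / RSS_null).
#'
#' @param genotype genotype vector (`"A"/"H"/"B"` or codes 1/2/3)
#' @param phenotype numeric phenotype vector
#' @return list with `a`, `d`, `pve`, `class_means`
#' @export
estimate_effects_pve <- function(genotype, phenotype) {
  g <- geno_to_int(genotype)
  ok <- !is.na(g) & !is.na(phenotype)
  g <- g[ok]; y <- phenotype[ok]
  mns <- tapply(y, factor(g, levels = 1:3), mean)
  rss1 <- sum((y - mns[g])^2)
  rss0 <- sum((y - mean(y))^2)
  a <- unname((mns[1] - mns[3]) / 2)
  d <- unname(mns[2] - (mns[1] + mns[3]) / 2)
  pve <- if (rss0 > 0) 100 * (1 - rss1 / rss0) else 0
  list(a = a, d = d, pve = pve, class_means = mns)
}

#' Map a trait locus end to end
#'
#' Convenience wrapper: encodes the bin genotypes, selects cofactors,
#' scans the genome, derives the permutation threshold and the LOD-drop
#' support interval.
#'
#' @param bg a [genotype_bins()] result
#' @param phenotype named or ordered phenotype vector (0/1 trait)
#' @param map optional pre-built [build_genetic_map()]
#' @param n_perm,alpha,lod_drop,step_cM,seed scan parameters
#' @param p_in,p_out stepwise thresholds
#' @param method scan method, as in [scan_icim()]
#' @return an object of class `qtl_result`
#' @export
map_qtl <- function(bg, phenotype, map = NULL, n_perm = 3000L,
                    alpha = 0.01, lod_drop = 3.0, step_cM = 1.0,
                    seed = 1L, p_in = 0.001, p_out = 0.002,
                    method = c("hk", "em")) {
  if (is.null(map)) map <- build_genetic_map(bg)
  method <- match.arg(method)
  design <- encode_f2_covariates(bg)
  cof <- select_cofactors_stepwise(design, phenotype, p_in, p_out)
  pre <- scan_precompute(map, design, step_cM)
  prof <- scan_run(pre, design, phenotype, cof, method = method)
  thr <- permutation_threshold(map, design, phenotype, n_perm = n_perm,
                               alpha = alpha, seed = seed,
                               step_cM = step_cM, p_in = p_in,
                               p_out = p_out, pre = pre, method = method)
  si <- support_interval(prof, lod_drop)
  structure(list(profile = prof, threshold = thr, support = si,
                 cofactors = cof, map = map, alpha = alpha,
                 n_perm = n_perm, lod_drop = lod_drop, seed = seed),
            class = "qtl_result")
}

#' @export
print.qtl_result <- function(x, ...) {
  pk <- x$support$peak
  cat("QTL scan: peak LOD", round(pk$lod, 2), "on", pk$lg, "at",
      round(pk$cM, 1), "cM (", pk$chrom, ":",
      format(round(pk$pos_bp), big.mark = ","), ")\n")
  cat("  a =", signif(pk$a, 3), " d =", signif(pk$d, 3),
      " PVE =", round(pk$pve, 2), "%\n")
  cat("  LOD threshold (alpha ", x$alpha, ", ", x$n_perm, " perms): ",
      round(as.numeric(x$threshold), 2),
      if (pk$lod > as.numeric(x$threshold)) "  [significant]" else
        "  [not significant]", "\n", sep = "")
  cat("  ", x$lod_drop, "-LOD support: ", round(x$support$cM_lo, 1), "-",
      round(x$support$cM_hi, 1), " cM (",
      format(round(x$support$bp_lo), big.mark = ","), "-",
      format(round(x$support$bp_hi), big.mark = ","), " bp)\n", sep = "")
  invisible(x)
}

#' Write a scan profile as TSV
#'
#' @param profile a `qtl_profile`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_scan_profile <- function(profile, path) {
  write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
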