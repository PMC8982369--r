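# Marker and animal quality control: call-rate and MAF filters, a forward
# adjacent-LD pruning pass, pairwise LD, and mean imputation.

# Minor allele frequency per SNP from observed dosages (pairwise-complete).
.maf <- function(dosages) {
  p <- colMeans(dosages, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Quality-control filter for a genotype panel
#'
#' Applies, in a fixed documented order: (1) animals with call rate below
#' `animal_callrate_min` are removed; (2) SNPs with call rate below
#' `snp_callrate_min` or minor allele frequency below `maf_min` (computed on
#' the surviving animals) are removed, call rate tallied first; (3) a single
#' forward pass within each chromosome compares every retained SNP with the
#' next retained SNP and, if the absolute Pearson correlation of their dosages
#' exceeds `adjacent_r_max`, removes one of the pair uniformly at random
#' (seeded).
#'
#' @param panel a `genotype_panel`.
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param snp_callrate_min minimum SNP call rate (default 0.90).
#' @param adjacent_r_max maximum |r| with the next retained SNP (default 0.80).
#' @param animal_callrate_min minimum animal call rate (default 0.90).
#' @param seed integer seed resolving which member of a correlated pair is
#'   dropped.
#' @return list with `panel` (filtered) and `report` (class `qc_report`):
#'   removal tallies per rule, surviving ids, thresholds and seed.
#' @export
qc_filter <- function(panel, maf_min = 0.05, snp_callrate_min = 0.90,
                      adjacent_r_max = 0.80, animal_callrate_min = 0.90,
                      seed = 1) {
  stopifnot(inherits(panel, "genotype_panel"))
  thr <- c(maf_min = maf_min, snp_callrate_min = snp_callrate_min,
           adjacent_r_max = adjacent_r_max, animal_callrate_min = animal_callrate_min)
  if (any(thr < 0) || any(thr > 1)) stop("thresholds must lie in [0, 1]")
  dos <- panel$dosages
  map <- panel$map

  animal_cr <- rowMeans(!is.na(dos))
  keep_animals <- animal_cr >= animal_callrate_min
  n_removed_animals <- sum(!keep_animals)
  dos <- dos[keep_animals, , drop = FALSE]
  if (nrow(dos) == 0) stop("QC error: no animals survive the call-rate filter")

  snp_cr <- colMeans(!is.na(dos))
  fail_cr <- snp_cr < snp_callrate_min
  maf <- .maf(dos)
  fail_maf <- !fail_cr & (is.na(maf) | maf < maf_min)
  n_removed_callrate_snp <- sum(fail_cr)
  n_removed_maf <- sum(fail_maf)
  keep <- !(fail_cr | fail_maf)

  removed_ld <- character(0)
  with_seed(seed, {
    for (ch in unique(map$chrom)) {
      idx <- which(map$chrom == ch & keep)
      if (length(idx) < 2) next
      i <- 1L
      while (i < length(idx)) {
        a <- idx[i]; b <- idx[i + 1L]
        r <- suppressWarnings(stats::cor(dos[, a], dos[, b],
                                         use = "pairwise.complete.obs"))
        if (!is.na(r) && abs(r) > adjacent_r_max) {
          drop_b <- stats::runif(1) < 0.5
          victim <- if (drop_b) b else a
          keep[victim] <- FALSE
          removed_ld <- c(removed_ld, colnames(dos)[victim])
          idx <- idx[idx != victim]
          # if the left member was dropped, the right member becomes the new
          # current SNP; either way compare it against the next retained SNP
        } else {
          i <- i + 1L
        }
      }
    }
  })
  if (!any(keep)) stop("QC error: no SNPs survive; report: ",
                       sprintf("animals=%d callrate=%d maf=%d ld=%d",
                               n_removed_animals, n_removed_callrate_snp,
                               n_removed_maf, length(removed_ld)))
  out <- genotype_panel(dos[, keep, drop = FALSE], map[keep, , drop = FALSE])
  report <- structure(list(
    n_removed_animals = n_removed_animals,
    n_removed_callrate_snp = n_removed_callrate_snp,
    n_removed_maf = n_removed_maf,
    n_removed_ld = length(removed_ld),
    removed_ld_snps = removed_ld,
    surviving_snps = colnames(out$dosages),
    surviving_animals = rownames(out$dosages),
    thresholds = thr, seed = seed), class = "qc_report")
  list(panel = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:\n",
      sprintf("  animals removed (call rate): %d\n", x$n_removed_animals),
      sprintf("  SNPs removed (call rate):    %d\n", x$n_removed_callrate_snp),
      sprintf("  SNPs removed (MAF):          %d\n", x$n_removed_maf),
      sprintf("  SNPs removed (adjacent LD):  %d\n", x$n_removed_ld),
      sprintf("  surviving: %d animals x %d SNPs\n",
              length(x$surviving_animals), length(x$surviving_snps)), sep = "")
  invisible(x)
}

#' Pairwise LD as squared Pearson correlation of dosages
#'
#' @param panel a `genotype_panel`.
#' @param pairs two-column matrix (or data.frame) of SNP indices or SNP ids.
#' @return numeric vector of r-squared values, one per pair, computed over
#'   animals non-missing at both SNPs.
#' @export
ld_r2 <- function(panel, pairs) {
  stopifnot(inherits(panel, "genotype_panel"))
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2)
  dos <- panel$dosages
  ix <- function(v) if (is.character(v)) match(v, colnames(dos)) else as.integer(v)
  i1 <- ix(pairs[, 1]); i2 <- ix(pairs[, 2])
  if (anyNA(i1) || anyNA(i2)) stop("unknown SNP in pairs")
  vapply(seq_along(i1), function(k) {
    x <- dos[, i1[k]]; y <- dos[, i2[k]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      stop("undefined LD: zero variance at one of the SNPs")
    }
    stats::cor(x[ok], y[ok])^2
  }, numeric(1))
}

#' Mean-impute missing dosages
#'
#' Missing entries are replaced by the SNP's observed mean dosage (fractional
#' values allowed downstream). SNPs that become constant after imputation are
#' flagged in the `"constant_snps"` attribute.
#'
#' @param panel a `genotype_panel`.
#' @return a complete `genotype_panel`.
#' @export
impute_mean <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  dos <- panel$dosages
  if (!anyNA(dos)) return(panel)
  mn <- colMeans(dos, na.rm = TRUE)
  if (anyNA(mn)) stop("fully missing SNP: should have been removed by call-rate QC")
  na_idx <- which(is.na(dos), arr.ind = TRUE)
  dos[na_idx] <- mn[na_idx[, 2]]
  out <- genotype_panel(dos, panel$map)
  const <- colnames(dos)[apply(dos, 2, function(v) max(v) == min(v))]
  attr(out, "constant_snps") <- const
  out
}
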