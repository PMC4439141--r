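#' Construct a dosage panel
#'
#' The basic genotype container: a samples x SNPs matrix of expected
#' minor-allele counts (dosages in `[0, 2]`) plus per-SNP metadata. The
#' per-SNP minor allele frequency is computed from the mean dosage,
#' `maf = min(m/2, 1 - m/2)`, so that imputation uncertainty contributes.
#'
#' @param dosage Numeric matrix, samples in rows, SNPs in columns, values in
#'   `[0, 2]`. Missing cells are imputed to the SNP mean dosage (count
#'   reported via `message()`).
#' @param snps `data.frame` with columns `id`, `chrom`, `pos`, `ref_allele`,
#'   `alt_allele` (one row per dosage column). `chrom`/`pos` may be `NA` when
#'   positional operations are not needed.
#' @param sample_ids Character vector of unique sample identifiers.
#' @param probs Optional samples x SNPs x 3 array of genotype probabilities
#'   (hom-ref, het, hom-alt); each triple must sum to 1 and be consistent
#'   with the dosage to `1e-6`.
#' @return An object of class `dosage_panel`.
#' @export
dosage_panel <- function(dosage, snps, sample_ids, probs = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
  if (length(sample_ids) != nrow(dosage)) stop("sample_ids/dosage mismatch")
  if (nrow(snps) != ncol(dosage)) stop("snps/dosage column mismatch")
  if (anyDuplicated(snps$id)) stop("duplicated SNP ids")
  n_miss <- sum(is.na(dosage))
  if (n_miss > 0) {
    message(sprintf("imputing %d missing dosage cells to SNP means", n_miss))
    for (j in seq_len(ncol(dosage))) {
      miss <- is.na(dosage[, j])
      if (any(miss)) dosage[miss, j] <- mean(dosage[!miss, j])
    }
  }
  if (any(dosage < -1e-9 | dosage > 2 + 1e-9)) stop("dosages outside [0, 2]")
  dosage <- pmin(pmax(dosage, 0), 2)
  if (!is.null(probs)) {
    sums <- apply(probs, c(1, 2), sum)
    if (any(abs(sums - 1) > 1e-6)) stop("genotype probability triples must sum to 1")
    implied <- probs[, , 2] + 2 * probs[, , 3]
    if (any(abs(implied - dosage) > 1e-6)) {
      stop("dosage inconsistent with genotype probabilities")
    }
  }
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos", "ref_allele", "alt_allele")
  for (col in setdiff(need, names(snps))) snps[[col]] <- NA
  snps <- snps[need]
  snps$chrom <- as.character(snps$chrom)
  snps$pos <- as.integer(snps$pos)
  if (any(!is.na(snps$pos) & snps$pos < 1)) stop("positions must be >= 1")
  snps$maf <- panel_maf(dosage)
  dimnames(dosage) <- list(sample_ids, snps$id)
  structure(list(sample_ids = as.character(sample_ids), snps = snps,
                 dosage = dosage, probs = probs),
            class = "dosage_panel")
}

#' @export
print.dosage_panel <- function(x, ...) {
  cat(sprintf("<dosage_panel> %d samples x %d SNPs%s\n",
              nrow(x$dosage), ncol(x$dosage),
              if (is.null(x$probs)) "" else " (+genotype probabilities)"))
  invisible(x)
}

#' @export
dim.dosage_panel <- function(x) dim(x$dosage)

# maf = min(mean/2, 1 - mean/2), per SNP column
panel_maf <- function(dosage) {
  m <- colMeans(dosage) / 2
  pmin(m, 1 - m)
}

# subset panel by SNP column index, keeping metadata/probs aligned
subset_snps <- function(panel, j) {
  dosage_panel(panel$dosage[, j, drop = FALSE],
               panel$snps[j, setdiff(names(panel$snps), "maf"), drop = FALSE],
               panel$sample_ids,
               probs = if (is.null(panel$probs)) NULL else
                 panel$probs[, j, , drop = FALSE])
}

#' Read a dosage panel from disk
#'
#' Two dialects are supported. `"tabular"` is a TSV with a header row of SNP
#' ids and the sample id in the first column (the fixture format written by
#' [write_dosage_tabular()]); optional SNP metadata (columns `id`, `chrom`,
#' `pos`, `ref_allele`, `alt_allele`) can be supplied via `snp_info`.
#' `"vcf"` reads a VCF carrying a per-genotype dosage field (`DS`) or
#' genotype-probability triples (`GP`); multi-allelic records are rejected
#' (split them upstream). VCF support uses the VariantAnnotation package.
#'
#' @param path File to read.
#' @param format `"tabular"` or `"vcf"`.
#' @param snp_info Optional SNP metadata for the tabular dialect: a
#'   `data.frame` or the path of a TSV with the columns listed above.
#' @return A [dosage_panel()].
#' @export
read_dosage <- function(path, format = c("tabular", "vcf"), snp_info = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tabular") {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stop("malformed tabular dosage file (need >= 2 columns): ", path)
    sample_ids <- as.character(tab[[1]])
    mat <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(mat)) {
      bad <- which(!vapply(tab[-1], is.numeric, logical(1)))[1]
      stop(sprintf("non-numeric dosage column '%s' in %s", names(tab)[-1][bad], path))
    }
    snps <- data.frame(id = colnames(mat), stringsAsFactors = FALSE)
    if (!is.null(snp_info)) {
      if (is.character(snp_info)) {
        snp_info <- read.delim(snp_info, stringsAsFactors = FALSE)
      }
      idx <- match(snps$id, snp_info$id)
      if (anyNA(idx)) stop("snp_info missing ids: ",
                           paste(head(snps$id[is.na(idx)], 5), collapse = ", "))
      snps <- snp_info[idx, , drop = FALSE]
    }
    return(dosage_panel(mat, snps, sample_ids))
  }
  read_dosage_vcf(path)
}

read_dosage_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("VCF input requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  if (any(S4Vectors::elementNROWS(alt) != 1)) {
    stop("multi-allelic records present; split them upstream")
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  snps <- data.frame(
    id = names(rr),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref_allele = as.character(VariantAnnotation::ref(vcf)),
    alt_allele = vapply(alt, function(a) as.character(a)[1], character(1)),
    stringsAsFactors = FALSE)
  g <- VariantAnnotation::geno(vcf)
  sample_ids <- colnames(vcf)
  if ("GP" %in% names(g)) {
    gp <- g$GP  # SNP x sample x 3 (or matrix of lists)
    if (is.list(gp)) {
      arr <- array(NA_real_, c(ncol(vcf), nrow(vcf), 3))
      for (i in seq_len(nrow(vcf))) for (s in seq_len(ncol(vcf))) {
        arr[s, i, ] <- gp[[i, s]]
      }
    } else {
      arr <- aperm(gp, c(2, 1, 3))
    }
    dos <- arr[, , 2, drop = FALSE][, , 1] + 2 * arr[, , 3, drop = FALSE][, , 1]
    dos <- matrix(dos, nrow = length(sample_ids))
    return(dosage_panel(dos, snps, sample_ids, probs = arr))
  }
  if ("DS" %in% names(g)) {
    dos <- t(g$DS)
    return(dosage_panel(dos, snps, sample_ids))
  }
  stop("VCF carries neither a DS dosage field nor GP genotype probabilities")
}

#' Write a dosage panel in the tabular fixture dialect
#'
#' Header row of SNP ids, sample id in the first column, tab-separated.
#' SNP metadata can be written alongside with `snp_info_path`.
#'
#' @param panel A [dosage_panel()].
#' @param path Output TSV path.
#' @param snp_info_path Optional path for a SNP metadata TSV.
#' @export
write_dosage_tabular <- function(panel, path, snp_info_path = NULL) {
  tab <- data.frame(sample_id = panel$sample_ids, panel$dosage,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(snp_info_path)) {
    write.table(panel$snps, snp_info_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Define a gene region
#'
#' A named genomic interval with a symmetric flank. Coordinates are 1-based
#' inclusive; the effective interval is
#' `[start - flank_bp, end + flank_bp]` clipped at 1, with inclusive bounds
#' on both flanked ends.
#'
#' @param name Region name.
#' @param chrom Chromosome label (matched as a string against SNP metadata).
#' @param start,end 1-based inclusive gene bounds, `start <= end`.
#' @param flank_bp Flank in base pairs on each side (default 5000).
#' @return One-row `data.frame` with class `gene_region` rows compatible with
#'   [read_regions()].
#' @export
gene_region <- function(name, chrom, start, end, flank_bp = 5000L) {
  if (any(start > end)) stop("start must be <= end")
  if (any(flank_bp < 0)) stop("flank_bp must be >= 0")
  data.frame(name = as.character(name), chrom = as.character(chrom),
             start = as.integer(start), end = as.integer(end),
             flank_bp = as.integer(flank_bp), stringsAsFactors = FALSE)
}

#' Read gene region definitions
#'
#' `"tsv"`: 4 columns (name, chrom, start, end), 1-based inclusive, header
#' optional `flank_bp` column. `"bed"`: 0-based half-open
#' (chrom, start, end, name), converted to 1-based inclusive.
#'
#' @param path File to read.
#' @param format `"tsv"` or `"bed"`.
#' @param flank_bp Flank applied to regions lacking their own (default 5000).
#' @return `data.frame` of regions as from [gene_region()].
#' @export
read_regions <- function(path, format = c("tsv", "bed"), flank_bp = 5000L) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    if (is.null(tab$flank_bp)) tab$flank_bp <- flank_bp
    return(gene_region(tab$name, tab$chrom, tab$start, tab$end, tab$flank_bp))
  }
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  gene_region(tab[[4]], tab[[1]], tab[[2]] + 1L, tab[[3]], flank_bp)
}

#' Filter SNPs on minor allele frequency
#'
#' Retains exactly the SNPs with `maf > threshold` (strict inequality,
#' matching the "common SNPs, MAF > 5%" restriction); SNP order is preserved.
#'
#' @param panel A [dosage_panel()].
#' @param threshold MAF threshold in `[0, 0.5)`; default 0.05.
#' @return Filtered [dosage_panel()] (possibly with zero SNPs).
#' @export
filter_maf <- function(panel, threshold = 0.05) {
  if (threshold < 0 || threshold >= 0.5) stop("threshold must be in [0, 0.5)")
  subset_snps(panel, which(panel$snps$maf > threshold))
}

#' Extract the SNPs falling in a flanked gene region
#'
#' Selects SNPs with matching chromosome and position inside
#' `[start - flank_bp, end + flank_bp]`, inclusive on both ends.
#'
#' @param panel A [dosage_panel()] whose SNPs carry `chrom`/`pos`.
#' @param region One-row region as from [gene_region()].
#' @return [dosage_panel()] restricted to the region (empty allowed, with a
#'   warning).
#' @export
extract_region <- function(panel, region) {
  if (nrow(region) != 1) stop("extract_region takes a single region row")
  lo <- max(1, region$start - region$flank_bp)
  hi <- region$end + region$flank_bp
  keep <- which(!is.na(panel$snps$pos) &
                  panel$snps$chrom == region$chrom &
                  panel$snps$pos >= lo & panel$snps$pos <= hi)
  if (length(keep) == 0) {
    warning(sprintf("region %s contains no SNPs", region$name))
  }
  subset_snps(panel, keep)
}

#' Convert dosages or genotype probabilities to best-call genotypes
#'
#' With genotype probabilities present, the call is the arg-max of each
#' triple; otherwise the dosage is rounded to the nearest integer in
#' `{0, 1, 2}`. Ties (probability ties, or dosages exactly at `.5`) break
#' toward the smaller minor-allele count.
#'
#' @param panel A [dosage_panel()].
#' @return The panel with integer calls in `{0, 1, 2}` as its dosage matrix,
#'   class `c("best_call_panel", "dosage_panel")`.
#' @export
best_call <- function(panel) {
  if (!is.null(panel$probs)) {
    calls <- apply(panel$probs, c(1, 2), which.max) - 1L  # which.max: first tie
  } else {
    d <- panel$dosage
    calls <- ifelse(d - floor(d) == 0.5, floor(d), round(d))
  }
  calls <- matrix(as.integer(pmin(pmax(calls, 0L), 2L)), nrow = nrow(panel$dosage),
                  dimnames = dimnames(panel$dosage))
  out <- panel
  out$dosage <- calls
  out$probs <- NULL
  out$snps$maf <- panel_maf(calls)
  class(out) <- c("best_call_panel", "dosage_panel")
  out
}

#' Leading genotype principal components
#'
#' Column-standardizes the dosage matrix (zero-variance SNPs skipped with a
#' warning) and returns the leading left singular vectors, the usual
#' population-structure covariates.
#'
#' @param panel A [dosage_panel()].
#' @param n_components Number of components (`<= min(samples, SNPs)`).
#' @return Numeric matrix (samples x `n_components`), columns `PC1`, `PC2`, ...
#' @export
compute_pcs <- function(panel, n_components) {
  X <- panel$dosage
  v <- apply(X, 2, var)
  if (any(v == 0)) {
    warning(sprintf("skipping %d zero-variance SNPs", sum(v == 0)))
    X <- X[, v > 0, drop = FALSE]
  }
  if (n_components == 0) {
    return(matrix(numeric(0), nrow = nrow(X), ncol = 0,
                  dimnames = list(panel$sample_ids, NULL)))
  }
  if (n_components > min(dim(X))) stop("n_components too large")
  Z <- scale(X)
  s <- svd(Z, nu = n_components, nv = 0)
  pcs <- s$u
  dimnames(pcs) <- list(panel$sample_ids, paste0("PC", seq_len(n_components)))
  pcs
}
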