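#' Read genotypes from a VCF file
#'
#' Biallelic records are loaded as an ALT-allele dosage matrix. The DS
#' (dosage) FORMAT field is preferred when present; otherwise hard GT
#' calls are converted to 0/1/2 (missing `./.` becomes `NA`). Multiallelic
#' records are skipped with a warning. The INFO `R2` imputation-quality
#' field is passed through when present.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param prefer `"DS"` (default) or `"GT"`.
#' @return list of class `geno_matrix` with `dosage` (samples x SNPs) and
#'   `map` (`snp`, `chr`, `pos`, `ref`, `alt`, `r2`). Coded (effect)
#'   allele is always ALT.
#' @export
read_genotypes <- function(path, prefer = c("DS", "GT")) {
  prefer <- match.arg(prefer)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- v@fix
  multi <- grepl(",", fx[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) skipped")
    v <- v[!multi, ]
    fx <- v@fix
  }
  has_ds <- any(grepl("DS", v@gt[, 1L], fixed = TRUE))
  if (prefer == "DS" && has_ds) {
    m <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    m <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    clean <- gsub("\\|", "/", gt)
    m[clean == "0/0"] <- 0
    m[clean %in% c("0/1", "1/0")] <- 1
    m[clean == "1/1"] <- 2
  }
  r2 <- suppressWarnings(as.numeric(vcfR::extract.info(v, "R2")))
  ids <- fx[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fx[, "CHROM"], ":", fx[, "POS"])[is.na(ids) | ids == "."]
  rownames(m) <- ids
  map <- data.frame(snp = ids, chr = fx[, "CHROM"],
                    pos = as.integer(fx[, "POS"]),
                    ref = fx[, "REF"], alt = fx[, "ALT"], r2 = r2,
                    stringsAsFactors = FALSE)
  structure(list(dosage = t(m), map = map), class = "geno_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write simulated genotypes as a VCF with GT, DS, and INFO/R2
#'
#' Plain-text VCF 4.2 writer for the synthetic-data path: hard calls are
#' emitted as GT, the same values as DS dosages, and an INFO `R2` field
#' (default 1.0, overridable per SNP) so that both the dosage path and the
#' imputation-quality filter can be exercised end to end.
#'
#' @param genotypes [simulate_genotypes()] result (integer dosages).
#' @param path output path.
#' @param r2 optional per-SNP imputation quality for INFO.
#' @export
write_vcf <- function(genotypes, path, r2 = NULL) {
  G <- genotypes$dosage
  map <- genotypes$map
  if (is.null(r2)) r2 <- rep(1, nrow(map))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"ALT dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(G)), collapse = "\t")), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(ncol(G))) {
    g <- G[, j]
    cell <- ifelse(is.na(g), "./.:.",
                   paste0(gt_code[as.character(g)], ":", format(g)))
    writeLines(paste(c(map$chr[j], map$pos[j], map$snp[j], map$ref[j],
                       map$alt[j], ".", "PASS",
                       sprintf("R2=%s", format(r2[j])), "GT:DS", cell),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write / read association result tables as TSV
#'
#' Numeric columns are written with full precision (17 significant
#' digits) so that `read_assoc(write_assoc(x))` round-trips to 1e-12.
#'
#' @param results an `assoc_result` (or any data frame).
#' @param path file path.
#' @export
write_assoc <- function(results, path) {
  df <- as.data.frame(results)
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  df[df == "NA"] <- NA
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_assoc
#' @export
read_assoc <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp", "beta", "se")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("association table is missing column(s): ", paste(miss, collapse = ", "))
  class(df) <- c("assoc_result", class(df))
  df
}
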