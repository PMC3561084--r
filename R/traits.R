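#' The default registry of the 77 IgG glycome traits
#'
#' The IgG N-glycome quantified by HILIC-UPLC yields 24 peak area
#' percentages (GP1..GP24) from which 77 traits (IGP1..IGP77) are computed:
#' 23 direct peak percentages and 54 derived traits. Derived traits are
#' percentages and ratios over structural classes (fucosylation,
#' galactosylation, sialylation, bisecting GlcNAc), many of them within the
#' *neutral* (asialylated) fraction of the glycome.
#'
#' Each trait is a `trait_spec` row with an arithmetic `expression` over the
#' peak ids and the class-aggregate function `cls(...)`, evaluated against a
#' normalized profile (see [evaluate_trait()]). The expression dialect:
#' peak ids `GP1`..`GP24` are percent-of-total values, and
#' `cls(fuc =, bis =, gal =, sia =, sia_min =)` sums the peaks whose major
#' structure matches the given constraints (`sia = 0` restricts to the
#' neutral fraction).
#'
#' Direct traits: by default two early co-eluting peaks are merged
#' (`IGP2 = GP2 + GP3`) so that the 24 peaks map onto 23 direct traits whose
#' per-sample values sum to 100; `direct_map = "one_to_one"` instead emits
#' 24 direct traits IGP1..IGP24 mapped 1:1.
#'
#' Derived traits beyond those pinned down by published descriptions
#' (e.g. IGP48 = 100*GP9/sum(neutral), IGP64 = fucosylated share of
#' monogalactosylated neutral structures) are best-effort class-aggregate
#' definitions; the registry is a plain TSV and fully user-overridable via
#' [read_trait_registry()].
#'
#' @param direct_map `"merged"` (default, 23 direct traits) or
#'   `"one_to_one"` (24 direct traits, no derived renumbering).
#' @return data frame of class `trait_registry` with columns `trait_id`,
#'   `kind` (`direct`, `percentage` or `ratio`), `expression`, `description`.
#' @export
default_trait_registry <- function(direct_map = c("merged", "one_to_one")) {
  direct_map <- match.arg(direct_map)
  path <- system.file("extdata", "igp_trait_registry.tsv", package = "glycogwas",
                      mustWork = TRUE)
  reg <- read_trait_registry(path)
  if (direct_map == "one_to_one") {
    direct <- data.frame(
      trait_id = sprintf("IGP%d", 1:24),
      kind = "direct",
      expression = sprintf("GP%d", 1:24),
      description = sprintf("Percentage of peak GP%d in total IgG glycans (1:1 map)", 1:24),
      stringsAsFactors = FALSE)
    reg <- rbind(direct, reg[reg$kind != "direct", ])
    rownames(reg) <- NULL
    class(reg) <- c("trait_registry", "data.frame")
  }
  reg
}

#' Read a trait registry TSV
#'
#' @param path TSV with columns `trait_id`, `kind`, `expression`,
#'   `description`.
#' @return a `trait_registry` data frame.
#' @export
read_trait_registry <- function(path) {
  reg <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("trait_id", "kind", "expression", "description")
  if (!all(need %in% names(reg)))
    stop("trait registry must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(reg$trait_id))
    stop("duplicate trait ids in registry")
  bad <- !reg$kind %in% c("direct", "percentage", "ratio")
  if (any(bad))
    stop("unknown trait kind(s): ", paste(unique(reg$kind[bad]), collapse = ", "))
  class(reg) <- c("trait_registry", "data.frame")
  reg
}

# Evaluation environment for trait expressions. `values` is a named list of
# per-peak numeric vectors (one element per sample); `cls` sums the peaks
# whose major structure matches the constraints.
trait_eval_env <- function(values, peak_table) {
  env <- new.env(parent = baseenv())
  for (p in names(values)) assign(p, values[[p]], envir = env)
  assign("cls", function(fuc = NULL, bis = NULL, gal = NULL, sia = NULL,
                         sia_min = NULL) {
    ids <- select_peaks(peak_table, fucosylated = fuc, bisecting = bis,
                        galactoses = gal, sialic_acids = sia,
                        min_sialic = sia_min)
    ids <- intersect(ids, names(values))
    if (length(ids) == 0L) return(0 * values[[1L]])
    Reduce(`+`, values[ids])
  }, envir = env)
  env
}

#' Evaluate one trait specification against glycome profiles
#'
#' @param spec one-row slice of a `trait_registry` (or a list with
#'   `trait_id`, `kind`, `expression`).
#' @param profiles matrix of normalized peak percentages (samples x peaks,
#'   columns named GP1..), see [normalize_profiles()].
#' @param peak_table a `peak_table`.
#' @return numeric vector, one value per sample. Zero denominators yield
#'   `NA` (missing value), not an error: real chromatograms can have empty
#'   peaks and downstream stages tolerate missing cells.
#' @export
evaluate_trait <- function(spec, profiles, peak_table) {
  profiles <- as.matrix(profiles)
  values <- lapply(seq_len(ncol(profiles)), function(j) profiles[, j])
  names(values) <- colnames(profiles)
  env <- trait_eval_env(values, peak_table)
  expr <- tryCatch(parse(text = spec$expression), error = function(e)
    stop(sprintf("trait %s: cannot parse expression '%s'", spec$trait_id,
                 spec$expression)))
  refs <- setdiff(all.vars(expr), "cls")
  missing_ref <- setdiff(refs, names(values))
  if (length(missing_ref) > 0L)
    stop(sprintf("trait %s references unknown peak id(s): %s", spec$trait_id,
                 paste(missing_ref, collapse = ", ")))
  out <- eval(expr[[1L]], env)
  out[!is.finite(out)] <- NA_real_
  out
}

#' Derive the full trait matrix from per-sample glycome profiles
#'
#' @param profiles matrix or data frame of peak values, samples in rows,
#'   columns GP1..GP24 (raw areas or percentages; rows are renormalized to
#'   sum to 100). Row names are sample ids and must be unique.
#' @param registry a `trait_registry` (default [default_trait_registry()]).
#' @param peak_table a `peak_table` (default [default_peak_table()]).
#' @return numeric matrix samples x traits with attribute
#'   `"n_missing"` (count of zero-denominator cells set to `NA`).
#' @examples
#' prof <- simulate_glycome_profiles(5, seed = 1)
#' igp <- derive_all_traits(prof)
#' rowSums(igp[, 1:23])  # direct traits are conserved: each row sums to 100
#' @export
derive_all_traits <- function(profiles, registry = default_trait_registry(),
                              peak_table = default_peak_table()) {
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles)))
    rownames(profiles) <- sprintf("S%d", seq_len(nrow(profiles)))
  if (anyDuplicated(rownames(profiles)))
    stop("duplicate sample ids in profiles")
  prof <- normalize_profiles(profiles)
  out <- matrix(NA_real_, nrow(prof), nrow(registry),
                dimnames = list(rownames(prof), registry$trait_id))
  for (i in seq_len(nrow(registry)))
    out[, i] <- evaluate_trait(registry[i, ], prof, peak_table)
  attr(out, "n_missing") <- sum(is.na(out))
  out
}

#' Read / write a glycome peak TSV (sample_id, GP1..GP24)
#'
#' Raw areas versus percentages are auto-detected from row sums (rows
#' summing to 100 within 0.5 are taken as already normalized); either way
#' values pass through [normalize_profiles()] downstream.
#'
#' @param path file path.
#' @return numeric matrix with sample ids as row names.
#' @export
read_glycome_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("glycome TSV needs a sample_id column")
  m <- as.matrix(df[setdiff(names(df), "sample_id")])
  rownames(m) <- df$sample_id
  m
}

#' @rdname read_glycome_tsv
#' @param profiles matrix as produced by the simulators or
#'   [normalize_profiles()].
#' @export
write_glycome_tsv <- function(profiles, path) {
  df <- data.frame(sample_id = rownames(profiles), as.data.frame(profiles),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a trait matrix as TSV (sample_id, IGP1..)
#'
#' Missing cells (zero denominators) are written as empty fields.
#'
#' @param traits samples x traits matrix from [derive_all_traits()].
#' @param path output path.
#' @export
write_trait_tsv <- function(traits, path) {
  df <- data.frame(sample_id = rownames(traits), as.data.frame(traits),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_trait_tsv
#' @export
read_trait_tsv <- function(path) {
  read_glycome_tsv(path)
}
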