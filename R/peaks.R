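#' Annotation of the 24 UPLC peaks of the IgG N-glycome
#'
#' Builds the peak table mapping each HILIC-UPLC chromatographic peak
#' (GP1..GP24) to the glycan structures it contains. Most peaks hold a
#' single structure; a few co-elute several, in which case the first listed
#' structure is the *major* contributor to fluorescence intensity and is the
#' one that decides class membership in derived-trait aggregates.
#'
#' The default annotation is transcribed by the package authors from the
#' published HILIC-UPLC separation of 2-AB labelled IgG glycans. Peak GP5
#' is dominated by an oligomannose species that falls outside the Oxford
#' grammar used here; it is annotated with an approximate complex-type
#' stand-in (`FA1B`) and should be overridden via [read_peak_table()] when a
#' better assignment is available. GP20 carries an uncertain assignment in
#' the source chromatogram and is annotated provisionally.
#'
#' @param path optional TSV with columns `peak_id`, `structures`
#'   (semicolon-separated Oxford names, major first) overriding the default.
#' @return A `peak_table`: data frame with one row per peak and columns
#'   `peak_id`, `major`, `structures` (list column of parsed structures),
#'   plus the major structure's features `core_fucose`, `antennae`,
#'   `bisecting`, `galactoses`, `gal_arm`, `sialic_acids`.
#' @seealso [select_peaks()], [derive_all_traits()]
#' @export
default_peak_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "uplc_peak_table.tsv", package = "glycogwas",
                        mustWork = TRUE)
  read_peak_table(path)
}

#' Read a UPLC peak annotation table
#'
#' @param path TSV with columns `peak_id` and `structures` (semicolon
#'   separated Oxford-notation names; the first is flagged as major).
#' @return a `peak_table`, see [default_peak_table()].
#' @export
read_peak_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("peak_id", "structures")
  if (!all(need %in% names(raw)))
    stop("peak table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(raw$peak_id))
    stop("duplicate peak ids in peak table: ",
         paste(unique(raw$peak_id[duplicated(raw$peak_id)]), collapse = ", "))
  structs <- lapply(strsplit(raw$structures, ";", fixed = TRUE), function(nms) {
    nms <- trimws(nms)
    nms <- nms[nzchar(nms)]
    if (length(nms) == 0L) stop("every peak needs at least one structure")
    lapply(nms, parse_glycan_name)
  })
  major <- lapply(structs, `[[`, 1L)
  out <- data.frame(
    peak_id = raw$peak_id,
    major = vapply(major, format_glycan_name, character(1)),
    core_fucose = vapply(major, `[[`, logical(1), "core_fucose"),
    antennae = vapply(major, `[[`, integer(1), "antennae"),
    bisecting = vapply(major, `[[`, logical(1), "bisecting"),
    galactoses = vapply(major, `[[`, integer(1), "galactoses"),
    gal_arm = vapply(major, `[[`, character(1), "gal_arm"),
    sialic_acids = vapply(major, `[[`, integer(1), "sialic_acids"),
    stringsAsFactors = FALSE)
  out$structures <- structs
  class(out) <- c("peak_table", class(out))
  out
}

#' Select peaks by structural class of their major glycan
#'
#' Class membership of a peak is decided by its *major* structure; minor
#' co-eluting structures are stored but ignored, matching the convention
#' that derived traits use only glycans with major contribution to
#' fluorescence intensity.
#'
#' @param peak_table a `peak_table` from [default_peak_table()].
#' @param fucosylated,bisecting logical or `NULL` (no constraint).
#' @param galactoses,sialic_acids exact counts or `NULL`.
#' @param min_sialic minimum sialic-acid count or `NULL`; `neutral = TRUE`
#'   is shorthand for `sialic_acids = 0`.
#' @param neutral logical or `NULL`.
#' @return character vector of peak ids whose major structure satisfies
#'   every supplied constraint (possibly empty).
#' @examples
#' pt <- default_peak_table()
#' select_peaks(pt, fucosylated = TRUE, galactoses = 1, neutral = TRUE)
#' @export
select_peaks <- function(peak_table, fucosylated = NULL, bisecting = NULL,
                         galactoses = NULL, sialic_acids = NULL,
                         min_sialic = NULL, neutral = NULL) {
  stopifnot(inherits(peak_table, "peak_table"))
  keep <- rep(TRUE, nrow(peak_table))
  if (!is.null(fucosylated)) keep <- keep & peak_table$core_fucose == fucosylated
  if (!is.null(bisecting)) keep <- keep & peak_table$bisecting == bisecting
  if (!is.null(galactoses)) keep <- keep & peak_table$galactoses == galactoses
  if (!is.null(sialic_acids)) keep <- keep & peak_table$sialic_acids == sialic_acids
  if (!is.null(min_sialic)) keep <- keep & peak_table$sialic_acids >= min_sialic
  if (!is.null(neutral)) keep <- keep & (peak_table$sialic_acids == 0L) == neutral
  peak_table$peak_id[keep]
}

#' Normalize raw peak areas to percent of total chromatogram area
#'
#' Peaks are quantified as relative contributions to the total IgG glycome:
#' each sample's areas are rescaled to sum to 100. Already-normalized input
#' is returned unchanged (up to floating point).
#'
#' @param areas numeric matrix or data frame, samples in rows, one column
#'   per peak; all values must be non-negative and each row must contain at
#'   least one strictly positive area.
#' @return matrix of the same shape with rows summing to 100.
#' @export
normalize_profiles <- function(areas) {
  x <- as.matrix(areas)
  if (!is.numeric(x)) stop("peak areas must be numeric")
  if (any(x < 0, na.rm = TRUE)) stop("peak areas must be non-negative")
  tot <- rowSums(x, na.rm = TRUE)
  bad <- tot <= 0
  if (any(bad))
    stop("degenerate profile: all-zero peak areas for sample(s) ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  sweep(x, 1L, tot / 100, "/")
}
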