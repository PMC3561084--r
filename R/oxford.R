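#' Parse an Oxford-notation glycan name
#'
#' Oxford nomenclature encodes the structural features of a complex N-glycan
#' as a compact token string: a leading `F` for a core fucose, `A<n>` for the
#' number of antennae (1-4), an optional `[3]`/`[6]` arm qualifier for a
#' single galactose, `B` for a bisecting GlcNAc, `G<n>` for the number of
#' galactoses and `S<n>` for the number of sialic acids. `FA2[3]G1` is a
#' core-fucosylated biantennary glycan with one galactose on the alpha 1-3
#' arm; `A2` is an agalactosylated biantennary glycan without core fucose.
#'
#' @param name character scalar, e.g. `"FA2G2S1"`.
#' @return An object of class `glycan_structure`: a list with fields
#'   `name` (canonical formatting), `core_fucose`, `antennae`, `bisecting`,
#'   `galactoses`, `gal_arm` (one of `"unspecified"`, `"arm3"`, `"arm6"`) and
#'   `sialic_acids`.
#' @details Structural sanity is enforced: sialic acids cannot outnumber
#'   galactoses, galactoses cannot outnumber antennae, and an arm qualifier
#'   is only meaningful for exactly one galactose. Violations and malformed
#'   token orders raise an error naming the offending token.
#' @examples
#' parse_glycan_name("FA2[3]G1")
#' parse_glycan_name("A2")
#' @export
parse_glycan_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name))
    stop("'name' must be a single glycan name string")
  name <- trimws(name)
  m <- regexec("^(F)?A([0-9])(\\[([36])\\])?(B)?(G([0-9]))?(S([0-9]))?$", name)
  parts <- regmatches(name, m)[[1]]
  if (length(parts) == 0L)
    stop(sprintf("cannot parse glycan name '%s': tokens must follow F? A<n> [3|6]? B? G<n>? S<n>?",
                 name))
  ant <- as.integer(parts[3])
  if (ant < 1L || ant > 4L)
    stop(sprintf("glycan '%s': antenna token A%d outside the supported range 1-4", name, ant))
  gal <- if (nzchar(parts[8])) as.integer(parts[8]) else 0L
  sia <- if (nzchar(parts[10])) as.integer(parts[10]) else 0L
  arm <- if (nzchar(parts[4])) paste0("arm", parts[5]) else "unspecified"
  if (gal > ant)
    stop(sprintf("glycan '%s': token G%d exceeds the antenna count A%d", name, gal, ant))
  if (sia > gal)
    stop(sprintf("glycan '%s': token S%d exceeds the galactose count G%d", name, sia, gal))
  if (arm != "unspecified" && gal != 1L)
    stop(sprintf("glycan '%s': arm qualifier [%s] requires exactly one galactose, found G%d",
                 name, parts[5], gal))
  out <- structure(
    list(name = NA_character_,
         core_fucose = nzchar(parts[2]),
         antennae = ant,
         bisecting = nzchar(parts[6]),
         galactoses = gal,
         gal_arm = arm,
         sialic_acids = sia),
    class = "glycan_structure")
  out$name <- format_glycan_name(out)
  out
}

#' Canonical Oxford-notation formatting of a parsed glycan
#'
#' Inverse of [parse_glycan_name()]: `format_glycan_name(parse_glycan_name(x))`
#' reproduces the canonical form of `x` (zero counts of G and S are omitted).
#'
#' @param x a `glycan_structure`.
#' @return character scalar.
#' @export
format_glycan_name <- function(x) {
  stopifnot(inherits(x, "glycan_structure"))
  paste0(if (x$core_fucose) "F" else "",
         "A", x$antennae,
         switch(x$gal_arm, arm3 = "[3]", arm6 = "[6]", ""),
         if (x$bisecting) "B" else "",
         if (x$galactoses > 0L) paste0("G", x$galactoses) else "",
         if (x$sialic_acids > 0L) paste0("S", x$sialic_acids) else "")
}

#' @export
print.glycan_structure <- function(x, ...) {
  cat("Glycan", x$name, "\n")
  cat(sprintf("  core fucose: %s | antennae: %d | bisecting GlcNAc: %s\n",
              x$core_fucose, x$antennae, x$bisecting))
  cat(sprintf("  galactoses: %d (%s) | sialic acids: %d\n",
              x$galactoses, x$gal_arm, x$sialic_acids))
  invisible(x)
}

#' @export
format.glycan_structure <- function(x, ...) format_glycan_name(x)
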