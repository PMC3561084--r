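#' Simulate a pedigree and its expected kinship matrix
#'
#' Generates families of one of three shapes: `"sibships"` (full sibs with
#' latent, unobserved parents -- the analysed samples are the sibs),
#' `"nuclear"` (two founder parents plus their offspring, all observed) or
#' `"unrelated"` (singletons). Expected kinship comes from path counting:
#' 0.5 with self, 0.25 for full sibs and parent-offspring, 0 otherwise.
#'
#' @param n_families number of families.
#' @param family_structure one of `"sibships"`, `"nuclear"`, `"unrelated"`.
#' @param family_size sibs per sibship / children per nuclear family
#'   (ignored for `"unrelated"`, where each family is one individual).
#' @param seed optional integer seed.
#' @return list with
#'   \item{pedigree}{data frame `fid`, `iid`, `father`, `mother`, `sex`
#'     (1 = male, 2 = female), `observed`}
#'   \item{kinship}{expected kinship matrix over the *observed* individuals}
#'   \item{observed}{ids of the observed individuals}
#' @export
simulate_pedigree <- function(n_families, family_structure = c("sibships", "nuclear", "unrelated"),
                              family_size = 2, seed = NULL) {
  family_structure <- match.arg(family_structure)
  if (!is.null(seed)) set.seed(seed)
  fid <- sprintf("F%04d", seq_len(n_families))
  if (family_structure == "unrelated") {
    ped <- data.frame(fid = fid, iid = paste0(fid, "_I1"),
                      father = "0", mother = "0",
                      sex = sample(1:2, n_families, replace = TRUE),
                      observed = TRUE, stringsAsFactors = FALSE)
  } else {
    s <- family_size
    per_fam <- function(f) {
      pa <- paste0(f, "_P1"); ma <- paste0(f, "_P2")
      data.frame(fid = f,
                 iid = c(pa, ma, paste0(f, "_O", seq_len(s))),
                 father = c("0", "0", rep(pa, s)),
                 mother = c("0", "0", rep(ma, s)),
                 sex = c(1L, 2L, sample(1:2, s, replace = TRUE)),
                 observed = c(rep(family_structure == "nuclear", 2L),
                              rep(TRUE, s)),
                 stringsAsFactors = FALSE)
    }
    ped <- do.call(rbind, lapply(fid, per_fam))
  }
  obs <- ped$iid[ped$observed]
  K <- diag(0.5, length(obs))
  dimnames(K) <- list(obs, obs)
  if (family_structure == "sibships") {
    # all observed members of a family are full sibs
    blk <- matrix(0.25, family_size, family_size)
    diag(blk) <- 0.5
    for (f in seq_len(n_families)) {
      at <- (f - 1L) * family_size + seq_len(family_size)
      K[at, at] <- blk
    }
  } else if (family_structure == "nuclear") {
    # parents unrelated to each other; parent-offspring and sibs at 0.25
    m <- family_size + 2L
    blk <- matrix(0.25, m, m)
    diag(blk) <- 0.5
    blk[1L, 2L] <- blk[2L, 1L] <- 0
    for (f in seq_len(n_families)) {
      at <- (f - 1L) * m + seq_len(m)
      K[at, at] <- blk
    }
  }
  list(pedigree = ped, kinship = K, observed = obs)
}

#' Write a FAM-style pedigree TSV
#'
#' Columns `fid`, `iid`, `father`, `mother`, `sex` ("0" marks a founder's
#' missing parent).
#'
#' @param pedigree the `pedigree` element of [simulate_pedigree()].
#' @param path output path.
#' @export
write_fam <- function(pedigree, path) {
  utils::write.table(pedigree[c("fid", "iid", "father", "mother", "sex")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
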