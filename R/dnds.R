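# Counting dN/dS estimator (Nei-Gojobori-style site enumeration, standard
# genetic code, no multiple-hit correction). Somatic mutation counts per
# sample are low, so the correction is immaterial here.

# Standard genetic code, codon -> amino acid ('*' = stop).
GENETIC_CODE_STD <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

BASES <- c("A", "C", "G", "T")

split_codons <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) %% 3 != 0) stop("CDS length is not a multiple of 3")
  if (grepl("[^ACGT]", seq)) stop("CDS contains non-ACGT characters")
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  aas <- GENETIC_CODE_STD[codons]
  if (any(aas == "*")) {
    stop("CDS contains an internal stop codon at codon ",
         which(aas == "*")[1])
  }
  codons
}

#' Expected nonsynonymous/synonymous site counts for one codon
#'
#' Enumerates all 9 single-nucleotide changes of the codon; each change
#' contributes 1/3 site to N (amino-acid altering, including changes to a
#' stop) or to S (silent). N + S = 3 for every codon.
#'
#' @param codon 3-letter codon string.
#' @return named numeric vector `c(n_sites = , s_sites = )`.
#' @export
codon_sites <- function(codon) {
  codon <- toupper(codon)
  aa <- GENETIC_CODE_STD[codon]
  if (is.na(aa)) stop("invalid codon: ", codon)
  n <- 0; s <- 0
  for (pos in 1:3) {
    for (b in setdiff(BASES, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (GENETIC_CODE_STD[mut] == aa) s <- s + 1 / 3 else n <- n + 1 / 3
    }
  }
  c(n_sites = n, s_sites = s)
}

#' Expected site counts over a set of coding sequences
#' @param cds named character vector of coding sequences (lengths multiples
#'   of 3, no internal stop codons).
#' @return named numeric vector `c(n_sites = , s_sites = )`; the two always
#'   sum to 3 x the total number of codons.
#' @export
cds_sites <- function(cds) {
  totals <- c(n_sites = 0, s_sites = 0)
  for (seq in cds) {
    for (codon in split_codons(seq)) totals <- totals + codon_sites(codon)
  }
  totals
}

classify_mutation <- function(seq, pos, ref, alt) {
  seq <- toupper(seq); ref <- toupper(ref); alt <- toupper(alt)
  if (pos < 1 || pos > nchar(seq)) stop("position ", pos, " out of bounds")
  if (substr(seq, pos, pos) != ref) {
    stop("reference base mismatch at position ", pos, ": CDS has ",
         substr(seq, pos, pos), ", mutation says ", ref)
  }
  codon_idx <- (pos - 1) %/% 3
  codon <- substr(seq, codon_idx * 3 + 1, codon_idx * 3 + 3)
  off <- (pos - 1) %% 3 + 1
  mut <- codon
  substr(mut, off, off) <- alt
  if (GENETIC_CODE_STD[mut] == GENETIC_CODE_STD[codon]) "S" else "N"
}

#' Counting dN/dS estimator
#'
#' Classifies each single-nucleotide mutation as nonsynonymous or synonymous
#' by codon translation under the standard genetic code, counts expected N/S
#' sites per codon by exhaustive enumeration of the 9 possible changes
#' ([codon_sites]), and returns
#' `omega = (n_obs / n_sites) / (s_obs / s_sites)`.
#'
#' @param mutations data.frame with columns `cds_id`, `pos` (1-based
#'   position within the CDS), `ref`, `alt` (single bases).
#' @param cds named character vector of coding sequences covering every
#'   `cds_id` in `mutations`.
#' @return list `n_obs`, `s_obs`, `n_sites`, `s_sites`, `omega` and
#'   `omega_defined` (FALSE, with `omega = NA`, when `s_obs == 0` and
#'   `n_obs > 0`; `omega = 0` when `n_obs == 0` and `s_obs > 0`), classed
#'   `lp_dnds`.
#' @export
dnds_ratio <- function(mutations, cds) {
  stopifnot(all(c("cds_id", "pos", "ref", "alt") %in% names(mutations)))
  missing_ids <- setdiff(unique(mutations$cds_id), names(cds))
  if (length(missing_ids)) stop("no CDS for id: ", missing_ids[1])
  n_obs <- 0L; s_obs <- 0L
  for (i in seq_len(nrow(mutations))) {
    cls <- classify_mutation(cds[[mutations$cds_id[i]]], mutations$pos[i],
                             mutations$ref[i], mutations$alt[i])
    if (cls == "N") n_obs <- n_obs + 1L else s_obs <- s_obs + 1L
  }
  sites <- cds_sites(cds)
  omega_defined <- s_obs > 0 || n_obs == 0
  omega <- if (s_obs > 0) {
    (n_obs / sites[["n_sites"]]) / (s_obs / sites[["s_sites"]])
  } else if (n_obs == 0) 0 else NA_real_
  structure(list(n_obs = n_obs, s_obs = s_obs,
                 n_sites = sites[["n_sites"]], s_sites = sites[["s_sites"]],
                 omega = omega, omega_defined = omega_defined),
            class = "lp_dnds")
}

#' @export
print.lp_dnds <- function(x, ...) {
  cat(sprintf("dN/dS: omega = %s (N %d / %.2f sites, S %d / %.2f sites)\n",
              if (x$omega_defined) sprintf("%.4f", x$omega) else "undefined (s_obs = 0)",
              x$n_obs, x$n_sites, x$s_obs, x$s_sites))
  invisible(x)
}

#' Change in dN/dS between two mutation sets
#'
#' Convenience wrapper for comparing selection pressure between two
#' timepoints (e.g. mutations private to T_n vs T_n+1).
#'
#' @param mutations_from,mutations_to mutation data.frames as in
#'   [dnds_ratio].
#' @param cds named character vector of coding sequences.
#' @return list `from`, `to` (each an `lp_dnds`) and `delta`
#'   (`omega_to - omega_from`, `NA` if either is undefined).
#' @export
dnds_delta <- function(mutations_from, mutations_to, cds) {
  a <- dnds_ratio(mutations_from, cds)
  b <- dnds_ratio(mutations_to, cds)
  delta <- if (a$omega_defined && b$omega_defined) b$omega - a$omega else NA_real_
  list(from = a, to = b, delta = delta)
}

#' Enumerate all single-nucleotide changes of a CDS
#'
#' Every (position, alt base) pair with alt differing from the reference —
#' the uniform mutational opportunity space used for neutral-calibration
#' simulations.
#'
#' @param cds_id identifier to record in the output.
#' @param seq coding sequence.
#' @return data.frame with columns `cds_id`, `pos`, `ref`, `alt`
#'   (3 x length rows).
#' @export
all_single_nt_changes <- function(cds_id, seq) {
  seq <- toupper(seq)
  refs <- strsplit(seq, "")[[1]]
  pos <- rep(seq_along(refs), each = 3)
  ref <- rep(refs, each = 3)
  alt <- unlist(lapply(refs, function(b) setdiff(BASES, b)), use.names = FALSE)
  data.frame(cds_id = cds_id, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}
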