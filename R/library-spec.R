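# Synthetic scFv construct: 5' vector flank + VL + (G4S)x3 linker + VH + 3'
# vector flank. Flank and linker sequences are fixed so they can serve as
# alignment anchors; they are synthetic stand-ins for real vector sequence.
SCFV_FLANK5 <- "CATGTGCCTAGGCTCGAGATCTGCAGCTGG"
SCFV_LINKER <- "GGTGGAGGCGGTTCAGGCGGAGGTGGCTCTGGCGGTGGCGGATCG" # (G4S)x3
SCFV_FLANK3 <- "ACTAGTGGCCAGGCCGGCCAGCACCATCAC"

#' Default five-residue heavy-chain randomisation scheme
#'
#' Two residues in HCDR1 and three in HFR3 of the heavy chain, randomised
#' with the degenerate codons RMN, YMY, NNK, MTN and RYN respectively.
#'
#' @return A [mutation_scheme()].
#' @export
default_mutation_scheme <- function() {
  mutation_scheme(
    positions = c(31L, 33L, 74L, 76L, 78L),
    codons = c("RMN", "YMY", "NNK", "MTN", "RYN"),
    labels = c("HCDR1", "HCDR1", "HFR3", "HFR3", "HFR3")
  )
}

#' Synthetic wild-type scFv template
#'
#' Builds a reproducible synthetic scFv nucleotide template (VL, linker, VH,
#' vector flanks) for simulation and as the reference for clone
#' identification. Coding regions are random sense codons (no internal
#' stops), deterministic for a given seed; at each designed position the
#' wild-type codon is chosen from the scheme's own degenerate set so the
#' wild-type clone is a legal library member.
#'
#' @param scheme A [mutation_scheme()] over the VH amino-acid sequence.
#' @param vl_aa_length,vh_aa_length Chain lengths in residues.
#' @param seed Integer RNG seed.
#' @return An object of class `scfv_template`: list with `flank5`, `vl_nt`,
#'   `linker_nt`, `vh_nt`, `flank3`, translations `vl_aa`/`vh_aa`, and the
#'   `scheme`.
#' @export
scfv_template <- function(scheme = default_mutation_scheme(),
                          vl_aa_length = 108, vh_aa_length = 120,
                          seed = 0) {
  stopifnot(inherits(scheme, "mutation_scheme"))
  if (nrow(scheme) && max(scheme$position) > vh_aa_length) {
    ws_abort("Scheme positions exceed the VH length.", "invalid_scheme")
  }
  withr::local_seed(seed)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  # avoid ATG-free issues: none needed; just sample sense codons
  vl_cod <- sample(sense, vl_aa_length, replace = TRUE)
  vh_cod <- sample(sense, vh_aa_length, replace = TRUE)
  for (i in seq_len(nrow(scheme))) {
    cs <- scheme$codon_set[[i]]
    cs <- cs[Biostrings::GENETIC_CODE[cs] != "*"]
    vh_cod[scheme$position[i]] <- sample(cs, 1)
  }
  vl_nt <- paste(vl_cod, collapse = "")
  vh_nt <- paste(vh_cod, collapse = "")
  structure(
    list(
      flank5 = SCFV_FLANK5, vl_nt = vl_nt, linker_nt = SCFV_LINKER,
      vh_nt = vh_nt, flank3 = SCFV_FLANK3,
      vl_aa = translate_nt(vl_nt), vh_aa = translate_nt(vh_nt),
      scheme = scheme
    ),
    class = "scfv_template"
  )
}

#' @export
print.scfv_template <- function(x, ...) {
  cat(sprintf("<scfv_template> VL %d aa | linker %d nt | VH %d aa; %d designed positions\n",
              nchar(x$vl_aa), nchar(x$linker_nt), nchar(x$vh_aa), nrow(x$scheme)))
  invisible(x)
}

translate_nt <- function(nt) {
  as.character(Biostrings::translate(Biostrings::DNAString(nt)))
}

#' Full construct sequence for a clone
#'
#' @param template An [scfv_template()].
#' @param vh_nt Optional VH nucleotide sequence overriding the wild type
#'   (a library clone's mutated VH).
#' @param vl_nt Optional VL override.
#' @return The flank5 + VL + linker + VH + flank3 nucleotide string.
#' @export
construct_nt <- function(template, vh_nt = NULL, vl_nt = NULL) {
  stopifnot(inherits(template, "scfv_template"))
  paste0(template$flank5, vl_nt %||% template$vl_nt, template$linker_nt,
         vh_nt %||% template$vh_nt, template$flank3)
}

#' Specify a degenerate scFv phage library for simulation
#'
#' Draws `n_clones` library members from the template's mutation scheme
#' (each designed position gets a codon sampled uniformly from its
#' degenerate set, rejecting stop codons), assigns clone abundances and
#' antigen reactivity, and fixes the sequencing error model used by
#' [simulate_reads()].
#'
#' @param template An [scfv_template()].
#' @param n_clones Number of distinct library members to draw.
#' @param n_reactive Number of clones marked antigen-reactive (AR).
#' @param abundance `"uniform"` or `"lognormal"` clone abundance profile.
#' @param sub_rate Per-base substitution rate of simulated reads.
#' @param frameshift_rate Per-read probability of a 1-nt indel.
#' @param lowq_rate Per-read probability of a low-quality (mean < Q20) read.
#' @param revcomp_frac Fraction of reads emitted as reverse complement
#'   (pooled sequencing is unoriented; default 0.5).
#' @param seed Integer RNG seed.
#' @return An object of class `library_spec`: list with `template`, `scheme`,
#'   a `clones` tibble (`clone_id`, `residues`, `assignments` list-column,
#'   `vh_nt`, `abundance`, `reactive`) and `error_model`.
#' @examples
#' spec <- library_spec(n_clones = 10, n_reactive = 2, seed = 1)
#' spec$clones
#' @export
library_spec <- function(template = scfv_template(),
                         n_clones = 50, n_reactive = 5,
                         abundance = c("uniform", "lognormal"),
                         sub_rate = 0, frameshift_rate = 0, lowq_rate = 0,
                         revcomp_frac = 0.5, seed = 0) {
  stopifnot(inherits(template, "scfv_template"))
  abundance <- match.arg(abundance)
  if (n_reactive > n_clones) {
    ws_abort("`n_reactive` cannot exceed `n_clones`.", "invalid_parameter")
  }
  for (r in c(sub_rate, frameshift_rate, lowq_rate, revcomp_frac)) {
    if (!is.finite(r) || r < 0 || r > 1) {
      ws_abort("Error-model rates must lie in [0, 1].", "invalid_parameter")
    }
  }
  scheme <- template$scheme
  withr::local_seed(seed)
  vh_codons <- substring(template$vh_nt,
                         seq(1, nchar(template$vh_nt), 3),
                         seq(3, nchar(template$vh_nt), 3))
  clones <- purrr::map(seq_len(n_clones), function(i) {
    cods <- purrr::map_chr(scheme$codon_set, function(cs) {
      cs <- cs[Biostrings::GENETIC_CODE[cs] != "*"]
      sample(cs, 1)
    })
    cod <- vh_codons
    cod[scheme$position] <- cods
    res <- unname(Biostrings::GENETIC_CODE[cods])
    tibble(
      clone_id = sprintf("C%03d", i),
      residues = paste(res, collapse = ""),
      assignments = list(res),
      vh_nt = paste(cod, collapse = "")
    )
  }) |> purrr::list_rbind()
  ab <- switch(abundance,
               uniform = rep(1 / n_clones, n_clones),
               lognormal = { a <- stats::rlnorm(n_clones, 0, 1); a / sum(a) })
  clones$abundance <- ab
  clones$reactive <- FALSE
  if (n_reactive > 0) {
    clones$reactive[sample.int(n_clones, n_reactive)] <- TRUE
  }
  structure(
    list(
      template = template, scheme = scheme, clones = clones,
      error_model = list(sub_rate = sub_rate, frameshift_rate = frameshift_rate,
                         lowq_rate = lowq_rate, revcomp_frac = revcomp_frac,
                         q_high = 36, q_low = 12)
    ),
    class = "library_spec"
  )
}

#' @export
print.library_spec <- function(x, ...) {
  cat(sprintf("<library_spec> %d clones (%d reactive); sub %g, frameshift %g, low-Q %g, RC %g\n",
              nrow(x$clones), sum(x$clones$reactive),
              x$error_model$sub_rate, x$error_model$frameshift_rate,
              x$error_model$lowq_rate, x$error_model$revcomp_frac))
  invisible(x)
}

#' Per-clone fluorescence intensity map
#'
#' Antigen-reactive clones produce phage that coats the well surface and is
#' labelled by the fluorescent reporter; non-reactive clones contribute only
#' background. Intensities are in arbitrary units of the 16-bit image.
#'
#' @param spec A [library_spec()].
#' @param reactive_intensity,nonreactive_intensity Well fluorescence above
#'   background for reactive / non-reactive clones (a.u.).
#' @return A named numeric vector, clone id -> intensity.
#' @export
clone_intensities <- function(spec, reactive_intensity = 1000,
                              nonreactive_intensity = 0) {
  stopifnot(inherits(spec, "library_spec"))
  setNames(ifelse(spec$clones$reactive, reactive_intensity, nonreactive_intensity),
           spec$clones$clone_id)
}
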