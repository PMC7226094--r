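#' Expand a degenerate (IUPAC) codon
#'
#' Expands a 3-symbol IUPAC pattern (e.g. `"NNK"`, `"RMN"`) into its concrete
#' codon set and translates each codon with the standard genetic code. Stop
#' codons are reported separately from the amino-acid set.
#'
#' @param codon A length-1 character string of 3 IUPAC nucleotide symbols.
#' @return A list with `codons` (character vector of concrete codons),
#'   `amino_acids` (sorted unique one-letter residues, stops excluded),
#'   `stop_codons` (the stop codons in the expansion, possibly empty) and
#'   `has_stop`.
#' @examples
#' expand_degenerate_codon("NNK") # 32 codons, 20 residues + TAG
#' @export
expand_degenerate_codon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || is.na(codon)) {
    ws_abort("`codon` must be a single 3-letter string.", "invalid_codon")
  }
  codon <- toupper(codon)
  letters3 <- strsplit(codon, "")[[1]]
  if (length(letters3) != 3L ||
      !all(letters3 %in% names(Biostrings::IUPAC_CODE_MAP))) {
    ws_abort(
      sprintf("`%s` is not a valid IUPAC nucleotide triplet.", codon),
      "invalid_codon"
    )
  }
  sets <- lapply(letters3, function(s) {
    strsplit(Biostrings::IUPAC_CODE_MAP[[s]], "")[[1]]
  })
  grid <- expand.grid(sets[[1]], sets[[2]], sets[[3]],
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  codons <- sort(paste0(grid[[1]], grid[[2]], grid[[3]]))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stops <- codons[aa == "*"]
  list(
    codons = codons,
    amino_acids = sort(unique(aa[aa != "*"])),
    stop_codons = stops,
    has_stop = length(stops) > 0L
  )
}

#' Define a degenerate-codon mutagenesis scheme
#'
#' A mutation scheme fixes which residues of a wild-type scFv heavy chain are
#' randomised and with which degenerate codon. Positions are 1-based indices
#' into the heavy-chain (VH) amino-acid sequence, strictly increasing.
#'
#' @param positions Integer vector of designed VH residue positions (1-based,
#'   strictly increasing).
#' @param codons Character vector of 3-letter IUPAC degenerate codons, one per
#'   position.
#' @param labels Optional region labels (e.g. `"HCDR1"`, `"HFR3"`), recycled
#'   if length 1.
#' @return A tibble of class `mutation_scheme` with columns `position`,
#'   `codon`, `label`, and list-columns `codon_set` and `aa_set` from
#'   [expand_degenerate_codon()].
#' @examples
#' mutation_scheme(c(31, 33, 74, 76, 78),
#'                 c("RMN", "YMY", "NNK", "MTN", "RYN"),
#'                 c("HCDR1", "HCDR1", "HFR3", "HFR3", "HFR3"))
#' @export
mutation_scheme <- function(positions, codons, labels = NA_character_) {
  positions <- as.integer(positions)
  if (length(positions) != length(codons)) {
    ws_abort("`positions` and `codons` must have equal length.", "invalid_scheme")
  }
  if (length(positions) && (any(diff(positions) <= 0) || any(positions < 1))) {
    ws_abort("`positions` must be strictly increasing and >= 1.", "invalid_scheme")
  }
  exp <- lapply(codons, expand_degenerate_codon)
  out <- tibble(
    position = positions,
    codon = toupper(codons),
    label = rep_len(labels, length(positions)),
    codon_set = lapply(exp, `[[`, "codons"),
    aa_set = lapply(exp, `[[`, "amino_acids")
  )
  class(out) <- c("mutation_scheme", class(out))
  out
}

#' Combinatorial complexity of a mutagenesis scheme
#'
#' Product over designed positions of the number of distinct variants each
#' degenerate codon encodes. At the nucleotide level this is the number of
#' codon combinations; at the amino-acid level, of residue combinations.
#' The empty scheme has complexity 1 (empty product).
#'
#' @param scheme A [mutation_scheme()].
#' @param level `"nt"` (codon variants, the default) or `"aa"` (residue
#'   variants).
#' @param exclude_stop Drop stop codons (`"nt"`) before taking the product;
#'   residue sets never include stops.
#' @return A numeric count.
#' @examples
#' sch <- mutation_scheme(c(31, 33, 74, 76, 78),
#'                        c("RMN", "YMY", "NNK", "MTN", "RYN"))
#' scheme_complexity(sch)        # 524288 codon combinations
#' scheme_complexity(sch, "aa")  # residue combinations
#' @export
scheme_complexity <- function(scheme, level = c("nt", "aa"), exclude_stop = FALSE) {
  stopifnot(inherits(scheme, "mutation_scheme"))
  level <- match.arg(level)
  if (nrow(scheme) == 0L) return(1)
  sizes <- purrr::map2_dbl(scheme$codon_set, scheme$aa_set, function(cs, as) {
    if (level == "aa") {
      length(as)
    } else if (exclude_stop) {
      sum(Biostrings::GENETIC_CODE[cs] != "*")
    } else {
      length(cs)
    }
  })
  prod(sizes)
}

#' Mutation frequency pattern over identified clones
#'
#' Tabulates, for each designed position of the scheme, the frequency of each
#' residue across a set of clones (unweighted by read count by default, i.e.
#' each clone counts once). Residues outside the codon's translation set are
#' pooled into an `"other"` bin.
#'
#' @param clones A tibble with a list-column `assignments`: per clone, a
#'   character vector of residues at the designed positions (in scheme
#'   order), as produced by [classify_mutations()] / [identify_clones()].
#' @param scheme A [mutation_scheme()].
#' @param weight Optional column name (string) with per-clone weights, e.g.
#'   `"read_count"` for read-weighted frequencies.
#' @return A tibble `position`, `label`, `residue`, `n`, `freq`; within each
#'   position the frequencies sum to 1.
#' @export
mutation_frequency <- function(clones, scheme, weight = NULL) {
  stopifnot(inherits(scheme, "mutation_scheme"))
  has_assign <- !purrr::map_lgl(clones$assignments, is.null) &
    purrr::map_int(clones$assignments, length) == nrow(scheme)
  if (!all(has_assign)) {
    warn(sprintf("%d clone(s) without designed-residue assignments skipped.",
                 sum(!has_assign)))
    clones <- clones[has_assign, , drop = FALSE]
  }
  if (nrow(clones) == 0L) {
    ws_abort("No clones with designed-residue assignments.", "invalid_input")
  }
  w <- if (is.null(weight)) rep(1, nrow(clones)) else clones[[weight]]
  long <- tibble(
    clone = rep(seq_len(nrow(clones)), each = nrow(scheme)),
    position = rep(scheme$position, nrow(clones)),
    label = rep(scheme$label, nrow(clones)),
    residue = unlist(clones$assignments, use.names = FALSE),
    w = rep(w, each = nrow(scheme))
  )
  allowed <- setNames(scheme$aa_set, as.character(scheme$position))
  long$residue <- purrr::map2_chr(long$residue, as.character(long$position),
                                  function(r, p) {
                                    if (r %in% allowed[[p]]) r else "other"
                                  })
  out <- long |>
    dplyr::group_by(.data$position, .data$label, .data$residue) |>
    dplyr::summarise(n = sum(.data$w), .groups = "drop_last") |>
    dplyr::mutate(freq = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  class(out) <- c("mutation_frequency", class(out))
  out
}

#' Plot a mutation frequency pattern
#'
#' Bar panel per designed position, residues on the x axis.
#'
#' @param object A [mutation_frequency()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mutation_frequency <- function(object, ...) {
  object$panel <- sprintf("%s pos %d", object$label, object$position)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$residue, y = .data$freq)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = "residue", y = "frequency",
                  title = "Mutation frequency at designed positions") +
    ggplot2::theme_minimal()
}
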