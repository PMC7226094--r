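#' Locate construct anchors in sequencing reads
#'
#' Aligns the 5' vector flank, the scFv linker and the 3' vector flank
#' semi-globally against each read (anchor global, read local; match +1,
#' mismatch -1, gap -2) on both strands, keeps the orientation with the
#' higher total score, and derives the VL and VH segment boundaries from the
#' anchor positions: VL spans (5' flank end, linker start), VH spans
#' (linker end, 3' flank start). A read whose best alignment of any anchor
#' falls below the identity floor is flagged `anchor_fail`.
#'
#' @param reads Tibble with `read_id`, `seq` and optionally `qual`
#'   (Phred+33).
#' @param template An [scfv_template()] supplying the anchors.
#' @param min_identity Per-anchor identity floor, fraction (default 0.8).
#' @return A tibble per read: `read_id`, `orientation` (`"fwd"`/`"rev"`),
#'   `anchor_fail`, extracted `vl_nt`, `vh_nt` and their quality substrings
#'   `vl_qual`, `vh_qual` (`NA` on anchor failure).
#' @export
locate_anchors <- function(reads, template, min_identity = 0.8) {
  stopifnot(inherits(template, "scfv_template"))
  if (nrow(reads) == 0L) {
    return(tibble(read_id = character(), orientation = character(),
                  anchor_fail = logical(), vl_nt = character(),
                  vh_nt = character(), vl_qual = character(),
                  vh_qual = character()))
  }
  anchors <- c(flank5 = template$flank5, linker = template$linker_nt,
               flank3 = template$flank3)
  if (any(!nzchar(anchors))) {
    ws_abort("Template anchors must be non-empty.", "invalid_input")
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  fwd <- Biostrings::DNAStringSet(reads$seq)
  rev <- Biostrings::reverseComplement(fwd)
  align_one <- function(subjects, anchor) {
    Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(rep(anchor, length(subjects))),
      subject = subjects, type = "global-local",
      substitutionMatrix = mat, gapOpening = 0, gapExtension = 2
    )
  }
  res <- purrr::map(list(fwd = fwd, rev = rev), function(ss) {
    al <- purrr::map(anchors, align_one, subjects = ss)
    list(
      score = Reduce(`+`, purrr::map(al, Biostrings::score)),
      pid = purrr::map(al, ~ Biostrings::pid(.x) / 100),
      start = purrr::map(al, ~ Biostrings::start(Biostrings::subject(.x))),
      end = purrr::map(al, ~ Biostrings::end(Biostrings::subject(.x)))
    )
  })
  use_rev <- res$rev$score > res$fwd$score
  pick <- function(field, name) {
    ifelse(use_rev, res$rev[[field]][[name]], res$fwd[[field]][[name]])
  }
  min_pid <- pmin(pick("pid", "flank5"), pick("pid", "linker"),
                  pick("pid", "flank3"))
  vl_s <- pick("end", "flank5") + 1L
  vl_e <- pick("start", "linker") - 1L
  vh_s <- pick("end", "linker") + 1L
  vh_e <- pick("start", "flank3") - 1L
  ordered <- vl_s <= vl_e & vh_s <= vh_e & vl_e < vh_s
  fail <- min_pid < min_identity | !ordered

  seqs <- ifelse(use_rev, as.character(rev), as.character(fwd))
  quals <- if ("qual" %in% names(reads)) {
    ifelse(use_rev,
           vapply(reads$qual, function(q) paste(rev(strsplit(q, "")[[1]]), collapse = ""), ""),
           reads$qual)
  } else {
    strrep("I", nchar(seqs))
  }
  tibble(
    read_id = reads$read_id,
    orientation = ifelse(use_rev, "rev", "fwd"),
    anchor_fail = fail,
    vl_nt = ifelse(fail, NA_character_, substr(seqs, vl_s, vl_e)),
    vh_nt = ifelse(fail, NA_character_, substr(seqs, vh_s, vh_e)),
    vl_qual = ifelse(fail, NA_character_, substr(quals, vl_s, vl_e)),
    vh_qual = ifelse(fail, NA_character_, substr(quals, vh_s, vh_e))
  )
}

mean_phred <- function(qual) {
  vapply(qual, function(q) {
    if (is.na(q) || !nzchar(q)) return(NA_real_)
    mean(as.integer(charToRaw(q)) - 33L)
  }, numeric(1), USE.NAMES = FALSE)
}

translate_segment <- function(nt) {
  vapply(nt, function(s) {
    if (is.na(s) || nchar(s) %% 3 != 0 || nchar(s) == 0) return(NA_character_)
    as.character(Biostrings::translate(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Validate extracted variable-chain segments
#'
#' Applies the sequence-level QC of the identification funnel to the VL/VH
#' segments of each read: `frameshift` when a segment length is not a
#' multiple of 3, `defective_chain` when it deviates from the template
#' length by more than `length_tol` nt, `internal_stop` when the in-frame
#' translation contains a stop before the final codon, and `low_quality`
#' when the mean base quality over the two segments is below `min_quality`.
#' In-frame segments are translated.
#'
#' @param segments Output of [locate_anchors()].
#' @param template The [scfv_template()].
#' @param min_quality Mean Phred floor (default Q20).
#' @param length_tol Allowed deviation from template segment length (nt).
#' @return `segments` with flags `frameshift`, `defective_chain`,
#'   `internal_stop`, `low_quality`, translations `vl_aa`, `vh_aa`, and
#'   `qc_pass`.
#' @export
validate_chains <- function(segments, template, min_quality = 20,
                            length_tol = 0) {
  stopifnot(inherits(template, "scfv_template"))
  exp_vl <- nchar(template$vl_nt); exp_vh <- nchar(template$vh_nt)
  lv <- ifelse(is.na(segments$vl_nt), NA_integer_, nchar(segments$vl_nt))
  lh <- ifelse(is.na(segments$vh_nt), NA_integer_, nchar(segments$vh_nt))
  segments$frameshift <- !is.na(lv) & !is.na(lh) & (lv %% 3 != 0 | lh %% 3 != 0)
  segments$defective_chain <- !is.na(lv) & !is.na(lh) &
    (abs(lv - exp_vl) > length_tol | abs(lh - exp_vh) > length_tol)
  q <- (mean_phred(segments$vl_qual) * lv + mean_phred(segments$vh_qual) * lh) /
    (lv + lh)
  segments$low_quality <- !is.na(q) & q < min_quality
  ok <- !segments$anchor_fail & !segments$frameshift
  segments$vl_aa <- NA_character_
  segments$vh_aa <- NA_character_
  segments$vl_aa[ok] <- translate_segment(segments$vl_nt[ok])
  segments$vh_aa[ok] <- translate_segment(segments$vh_nt[ok])
  has_stop <- function(aa) {
    !is.na(aa) & grepl("\\*", substr(aa, 1, nchar(aa) - 1))
  }
  segments$internal_stop <- has_stop(segments$vl_aa) | has_stop(segments$vh_aa)
  segments$qc_pass <- !segments$anchor_fail & !segments$frameshift &
    !segments$defective_chain & !segments$low_quality & !segments$internal_stop
  segments
}

#' Classify designed and unintended mutations
#'
#' Compares each read's translated chains to the wild type. Residues at the
#' scheme's designed VH positions are recorded as assignments; a designed
#' residue outside its degenerate codon's translation set counts as one
#' unintended mismatch, as does every difference from wild type at any
#' non-designed position (VL or VH).
#'
#' @param records Output of [validate_chains()] (rows failing QC are passed
#'   through unclassified).
#' @param template The [scfv_template()].
#' @param scheme A [mutation_scheme()]; defaults to the template's.
#' @return `records` with list-column `assignments` (designed residues in
#'   scheme order) and `unintended` (count, `NA` where unclassifiable).
#' @export
classify_mutations <- function(records, template, scheme = template$scheme) {
  stopifnot(inherits(template, "scfv_template"))
  wt_vl <- strsplit(template$vl_aa, "")[[1]]
  wt_vh <- strsplit(template$vh_aa, "")[[1]]
  designed <- scheme$position
  res <- purrr::map(seq_len(nrow(records)), function(i) {
    vl <- records$vl_aa[i]; vh <- records$vh_aa[i]
    if (is.na(vl) || is.na(vh) ||
        nchar(vl) != length(wt_vl) || nchar(vh) != length(wt_vh)) {
      return(list(assignments = NULL, unintended = NA_integer_))
    }
    vl <- strsplit(vl, "")[[1]]; vh <- strsplit(vh, "")[[1]]
    assigned <- vh[designed]
    off_codon <- sum(!purrr::map2_lgl(assigned, scheme$aa_set, ~ .x %in% .y))
    non_designed <- setdiff(seq_along(wt_vh), designed)
    unint <- sum(vl != wt_vl) + sum(vh[non_designed] != wt_vh[non_designed]) +
      off_codon
    list(assignments = assigned, unintended = as.integer(unint))
  })
  records$assignments <- purrr::map(res, "assignments")
  records$unintended <- purrr::map_int(res, "unintended")
  records
}

#' Deduplicate reads into unique clones
#'
#' Merges classified reads by their amino-acid clone key (VL and VH
#' concatenated), summing read counts. `top_share()` reports the fraction
#' of all reads carried by the `k` most frequent clones.
#'
#' @param records Classified records with `vl_aa`, `vh_aa` (one row per
#'   read, or with a `read_count` column to carry pre-aggregated counts).
#' @return A tibble per unique clone, sorted by descending `read_count`:
#'   `clone_key`, `vl_aa`, `vh_aa`, `assignments`, `unintended`,
#'   `read_count`, `read_ids`.
#' @export
dedupe_and_count <- function(records) {
  if (nrow(records) == 0L) {
    return(tibble(clone_key = character(), vl_aa = character(),
                  vh_aa = character(), assignments = list(),
                  unintended = integer(), read_count = integer(),
                  read_ids = list()))
  }
  if (!"read_count" %in% names(records)) records$read_count <- rep(1L, nrow(records))
  if (!"read_id" %in% names(records)) records$read_id <- as.character(seq_len(nrow(records)))
  records$clone_key <- paste(records$vl_aa, records$vh_aa, sep = "|")
  records |>
    dplyr::group_by(.data$clone_key) |>
    dplyr::summarise(
      vl_aa = .data$vl_aa[1],
      vh_aa = .data$vh_aa[1],
      assignments = list(.data$assignments[[1]]),
      unintended = .data$unintended[1],
      read_count = sum(.data$read_count),
      read_ids = list(.data$read_id),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$read_count), .data$clone_key)
}

#' @rdname dedupe_and_count
#' @param read_counts Integer vector of per-clone read counts.
#' @param k Number of top clones.
#' @return `top_share()`: the fraction of total reads in the top `k` clones.
#' @examples
#' top_share(c(1823, 584, rep(1, 10)), k = 2)
#' @export
top_share <- function(read_counts, k) {
  if (length(read_counts) == 0L) return(NA_real_)
  sum(head(sort(read_counts, decreasing = TRUE), k)) / sum(read_counts)
}

#' Filter clones by unintended-mismatch count
#'
#' Keeps clones with no fatal QC flag and at most `max_unintended`
#' unintended amino-acid mismatches. The strict filter (`max_unintended =
#' 0`) retains only clones whose mutations are restricted to the randomised
#' residues; the relaxed filter (`max_unintended = 2`) additionally admits
#' up to two off-target mismatches (e.g. PCR-introduced).
#'
#' @param clones Tibble from [dedupe_and_count()] (or classified per-read
#'   records) with an `unintended` column.
#' @param max_unintended Maximum unintended mismatches retained.
#' @return The kept subset, same columns.
#' @export
filter_clones <- function(clones, max_unintended = 0) {
  keep <- !is.na(clones$unintended) & clones$unintended <= max_unintended
  clones[keep, , drop = FALSE]
}

#' Run the full clone-identification funnel
#'
#' Applies, in order: anchor location ([locate_anchors()]), chain QC
#' ([validate_chains()]), mutation classification
#' ([classify_mutations()]), deduplication by amino-acid clone key
#' ([dedupe_and_count()]), and the strict (0 unintended mismatches) and
#' relaxed (<= `relaxed_max`) filters.
#'
#' @param reads Tibble with `read_id`, `seq`, `qual` (or a FASTQ path).
#' @param library A [library_spec()] (its template and scheme are used).
#' @param min_identity Anchor identity floor.
#' @param min_quality Mean Phred floor.
#' @param relaxed_max Mismatch allowance of the relaxed filter (default 2).
#' @return An object of class `clone_id_result`: list with `records`
#'   (per-read), `clones` (all unique clones), `clones_strict`,
#'   `clones_relaxed`, and `report`, a funnel tibble of stage counts.
#' @export
identify_clones <- function(reads, library, min_identity = 0.8,
                            min_quality = 20, relaxed_max = 2) {
  stopifnot(inherits(library, "library_spec"))
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  template <- library$template
  seg <- locate_anchors(reads, template, min_identity = min_identity)
  seg <- validate_chains(seg, template, min_quality = min_quality)
  seg <- classify_mutations(seg, template)
  usable <- seg[seg$qc_pass & !is.na(seg$unintended), , drop = FALSE]
  clones <- dedupe_and_count(usable)
  strict <- filter_clones(clones, 0)
  relaxed <- filter_clones(clones, relaxed_max)
  n <- nrow(seg)
  report <- tibble(
    stage = c("input_reads", "anchor_fail", "low_quality",
              "frameshift_or_defective", "internal_stop", "reads_kept",
              "unique_clones", "clones_strict", "clones_relaxed"),
    count = c(
      n,
      sum(seg$anchor_fail),
      sum(!seg$anchor_fail & seg$low_quality),
      sum(!seg$anchor_fail & !seg$low_quality &
            (seg$frameshift | seg$defective_chain)),
      sum(!seg$anchor_fail & !seg$low_quality & !seg$frameshift &
            !seg$defective_chain & seg$internal_stop),
      nrow(usable),
      nrow(clones),
      nrow(strict),
      nrow(relaxed)
    )
  )
  structure(
    list(records = seg, clones = clones, clones_strict = strict,
         clones_relaxed = relaxed, report = report),
    class = "clone_id_result"
  )
}

#' @export
print.clone_id_result <- function(x, ...) {
  cat("<clone_id_result>\n")
  print(x$report, n = Inf)
  invisible(x)
}

#' @export
tidy.clone_id_result <- function(x, ...) x$clones

#' @export
glance.clone_id_result <- function(x, ...) {
  cnt <- setNames(x$report$count, x$report$stage)
  tibble(
    input_reads = cnt[["input_reads"]],
    reads_kept = cnt[["reads_kept"]],
    unique_clones = cnt[["unique_clones"]],
    clones_strict = cnt[["clones_strict"]],
    clones_relaxed = cnt[["clones_relaxed"]],
    top2_read_share = top_share(x$clones$read_count, 2)
  )
}
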