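#' Simulate pooled sequencing reads of scFv clones
#'
#' Emits reads of the full construct (5' flank + VL + linker + VH + 3'
#' flank) for the requested clones, planting errors at the library's
#' configured rates: per-base substitutions, per-read 1-nt frameshifts
#' (insertion or deletion, equally likely), low-quality reads (mean base
#' quality below Q20), and a configurable fraction emitted as the reverse
#' complement (pooled amplicon sequencing is unoriented). Every planted
#' defect is recorded as ground truth.
#'
#' @param library A [library_spec()] (its `error_model` sets the rates).
#' @param clone_counts Named integer vector: reads to emit per clone id.
#' @param seed Integer RNG seed.
#' @return A tibble with `read_id`, `clone_id`, `seq`, `qual` (Phred+33),
#'   and ground-truth columns `n_subs`, `frameshift`, `fs_region` (which
#'   construct segment took the indel), `low_quality`, `revcomp`.
#' @examples
#' spec <- library_spec(n_clones = 3, n_reactive = 1, seed = 1)
#' reads <- simulate_reads(spec, c(C001 = 2, C002 = 1), seed = 1)
#' @export
simulate_reads <- function(library, clone_counts, seed = 0) {
  stopifnot(inherits(library, "library_spec"))
  clone_counts <- clone_counts[clone_counts > 0]
  if (length(clone_counts) == 0L) {
    return(tibble(read_id = character(), clone_id = character(),
                  seq = character(), qual = character(),
                  n_subs = integer(), frameshift = logical(),
                  fs_region = character(), low_quality = logical(),
                  revcomp = logical()))
  }
  unknown <- setdiff(names(clone_counts), library$clones$clone_id)
  if (length(unknown) || is.null(names(clone_counts))) {
    ws_abort(sprintf("Unknown clone id(s): %s",
                     paste(unknown, collapse = ", ")), "invalid_input")
  }
  em <- library$error_model
  vh <- setNames(library$clones$vh_nt, library$clones$clone_id)
  withr::local_seed(seed)
  bases <- c("A", "C", "G", "T")

  clone_of_read <- rep(names(clone_counts), times = clone_counts)
  reads <- purrr::imap(clone_of_read, function(cid, i) {
    s <- strsplit(construct_nt(library$template, vh_nt = vh[[cid]]), "")[[1]]
    L <- length(s)
    n_sub <- rbinom(1, L, em$sub_rate)
    if (n_sub > 0) {
      pos <- sample.int(L, n_sub)
      s[pos] <- vapply(s[pos], function(b) sample(setdiff(bases, b), 1), "")
    }
    fs <- runif(1) < em$frameshift_rate
    fs_region <- NA_character_
    if (fs) {
      p <- sample.int(L, 1)
      cum <- cumsum(c(nchar(library$template$flank5), nchar(library$template$vl_nt),
                      nchar(library$template$linker_nt), nchar(vh[[cid]]),
                      nchar(library$template$flank3)))
      fs_region <- c("flank5", "vl", "linker", "vh", "flank3")[
        findInterval(p - 1, cum) + 1]
      if (runif(1) < 0.5) {
        s <- s[-p]
      } else {
        s <- append(s, sample(bases, 1), after = p)
      }
    }
    lowq <- runif(1) < em$lowq_rate
    q <- if (lowq) {
      pmin(pmax(round(rnorm(length(s), em$q_low, 3)), 2), 19)
    } else {
      pmin(pmax(round(rnorm(length(s), em$q_high, 2)), 25), 40)
    }
    seq <- paste(s, collapse = "")
    qual <- rawToChar(as.raw(q + 33L))
    rc <- runif(1) < em$revcomp_frac
    if (rc) {
      seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
      qual <- paste(rev(strsplit(qual, "")[[1]]), collapse = "")
    }
    tibble(read_id = sprintf("read_%05d", i), clone_id = cid, seq = seq,
           qual = qual, n_subs = n_sub, frameshift = fs,
           fs_region = fs_region, low_quality = lowq, revcomp = rc)
  })
  purrr::list_rbind(reads)
}

#' Read and write FASTQ (Phred+33)
#'
#' Thin wrappers around Biostrings' quality-scaled string sets that move
#' reads between the tibble representation used throughout the package and
#' standard FASTQ files.
#'
#' @param reads A tibble with `read_id`, `seq`, `qual`.
#' @param path FASTQ file path (uncompressed).
#' @return `read_fastq()` returns a tibble `read_id`, `seq`, `qual`;
#'   `write_fastq()` returns `path` invisibly.
#' @export
write_fastq <- function(reads, path) {
  # Biostrings warns that (empty) metadata columns are dropped when the
  # quality-scaled set is assembled from a named vector; harmless here
  suppressWarnings({
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id)),
      Biostrings::PhredQuality(reads$qual)
    )
    Biostrings::writeQualityScaledXStringSet(x, path)
  })
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  # same harmless metadata-column note as in write_fastq
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  tibble(
    read_id = names(x),
    seq = unname(as.character(x)),
    qual = unname(as.character(Biostrings::quality(x)))
  )
}
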