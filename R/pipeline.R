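#' Configuration for an end-to-end simulated screen
#'
#' Collects every tunable of the simulate - image - register - retrieve -
#' identify - confirm pipeline with defaults mirroring the platform's
#' standard operating point: lambda = 0.1 cells/well, 60 x 40 um wells on an
#' 85 um pitch, 3328 um tile field of view, hit and ELISA thresholds at
#' mean + 5 SD, 48 targets pooled per tube.
#'
#' `read_error` is the per-READ error probability of the (consensus-grade)
#' simulated sequencing; it is converted internally to the equivalent
#' per-base substitution rate of [simulate_reads()].
#'
#' @param n_rows,n_cols,pitch,well_diameter,well_depth,pixel_size,tile_fov
#'   Chip geometry; see [chip_layout()].
#' @param lambda Mean cells per well.
#' @param n_clones,n_reactive Library size and number of antigen-reactive
#'   members.
#' @param reactive_intensity Well fluorescence of reactive clones (a.u.).
#' @param image_noise_sd Gaussian pixel noise SD (a.u.).
#' @param overlap Tile overlap fraction.
#' @param hit_k,elisa_k SD multipliers of the imaging and ELISA thresholds.
#' @param distortion A [planar_transform()]: the ground-truth disassembly
#'   distortion.
#' @param marker_jitter_sd Marker localisation jitter (um).
#' @param reads_per_spot Sequencing reads per retrieved spot.
#' @param read_error Per-read error probability (see above).
#' @param frameshift_rate,lowq_rate,revcomp_frac Read error model; see
#'   [library_spec()].
#' @param pool_size Retrieval targets per tube.
#' @param n_negative,n_positive,neg_mean,neg_sd ELISA plate design; see
#'   [simulate_elisa()].
#' @return A named list of class `screen_config`.
#' @export
screen_config <- function(n_rows = 40, n_cols = 50, pitch = 85,
                          well_diameter = 60, well_depth = 40,
                          pixel_size = 3.25, tile_fov = 3328,
                          lambda = 0.1, n_clones = 50, n_reactive = 5,
                          reactive_intensity = 1000, image_noise_sd = 0,
                          overlap = 0.1, hit_k = 5, elisa_k = 5,
                          distortion = similarity_transform(1.01, 0.5, 12.3, -4.5),
                          marker_jitter_sd = 0,
                          reads_per_spot = 20, read_error = 0,
                          frameshift_rate = 0, lowq_rate = 0,
                          revcomp_frac = 0.5, pool_size = 48,
                          n_negative = 8, n_positive = 2,
                          neg_mean = 0.15, neg_sd = 0.05) {
  cfg <- as.list(environment())
  class(cfg) <- "screen_config"
  cfg
}

stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 20000L) * 100003L + stage
}

#' Run a complete simulated single-clone screen
#'
#' Executes the whole pipeline on synthetic data with known ground truth:
#' Poisson loading of a clonal phage library, tile rendering of both
#' channels, stitching, well detection, occupancy and fluorescence
#' quantification, hit calling, marker-based affine registration onto the
#' distorted sample-capturing substrate, retrieval planning, pooled read
#' simulation of the retrieved spots, the clone-identification funnel, and
#' ELISA confirmation of the strict-filtered clones.
#'
#' @param config A [screen_config()].
#' @param seed Integer master seed; each stochastic stage derives its own
#'   seed from it, so a fixed seed reproduces the run byte for byte.
#' @return An object of class `screen_run` with the per-stage inputs and
#'   outputs (`layout`, `library`, `occupancy`, `truth`, `hits`, `fit`,
#'   `plan`, `reads`, `ident`, `plate`, `elisa`), the `funnel` tibble, an
#'   `evaluation` (AR-clone recall/precision against planted ground truth)
#'   and a `manifest` (config snapshot, seeds, funnel).
#' @export
run_screen <- function(config = screen_config(), seed = 0) {
  stopifnot(inherits(config, "screen_config"))
  cfg <- config
  layout <- chip_layout(cfg$n_rows, cfg$n_cols, cfg$pitch, cfg$well_diameter,
                        cfg$well_depth, cfg$pixel_size, cfg$tile_fov)

  construct_len <- nchar(construct_nt(scfv_template()))
  sub_rate <- 1 - (1 - cfg$read_error)^(1 / construct_len)
  library <- library_spec(
    n_clones = cfg$n_clones, n_reactive = cfg$n_reactive,
    sub_rate = sub_rate, frameshift_rate = cfg$frameshift_rate,
    lowq_rate = cfg$lowq_rate, revcomp_frac = cfg$revcomp_frac,
    seed = stage_seed(seed, 1L)
  )
  occupancy <- simulate_loading(layout, cfg$lambda, library,
                                seed = stage_seed(seed, 2L))
  intensity <- clone_intensities(library, cfg$reactive_intensity)
  bf <- render_tiles(layout, occupancy, intensity, "brightfield",
                     noise_sd = cfg$image_noise_sd, overlap = cfg$overlap,
                     seed = stage_seed(seed, 3L))
  fl <- render_tiles(layout, occupancy, intensity, "fluorescence",
                     noise_sd = cfg$image_noise_sd, overlap = cfg$overlap,
                     seed = stage_seed(seed, 4L))
  sb <- stitch_tiles(bf)
  sf <- stitch_tiles(fl)
  r_meas <- 0.8 * cfg$well_diameter / 2
  cent <- detect_wells(sb, layout)
  cent <- call_occupancy(sb, cent, well_radius_um = r_meas)
  meas <- measure_wells(sf, cent, well_radius_um = r_meas)
  hits <- call_hits(meas, k = cfg$hit_k)

  markers_post <- apply_disassembly_distortion(
    layout$markers, cfg$distortion, jitter_sd = cfg$marker_jitter_sd,
    seed = stage_seed(seed, 5L)
  )
  fit <- fit_transform(layout$markers, markers_post)
  hit_wells <- hits$wells[hits$wells$hit, , drop = FALSE]
  substrate <- map_coordinates(fit, hit_wells[c("row", "col", "x_um", "y_um")])
  plan <- plan_retrieval(substrate, pool_size = cfg$pool_size)

  # retrieval is assumed exact: registration accuracy (~um) is far inside
  # the 60 um well; each spot yields reads of the clones seeded in its well
  spot_clones <- dplyr::left_join(
    plan[c("target_id", "row", "col")],
    occupancy[c("row", "col", "clone_ids")],
    by = c("row", "col")
  )
  withr::with_seed(stage_seed(seed, 6L), {
    counts <- table(unlist(purrr::map(spot_clones$clone_ids, function(ids) {
      if (!length(ids)) character(0)
      else sample(ids, cfg$reads_per_spot, replace = TRUE)
    })))
  })
  clone_counts <- setNames(as.integer(counts), names(counts))
  reads <- simulate_reads(library, clone_counts, seed = stage_seed(seed, 7L))
  ident <- identify_clones(reads, library)

  strict <- ident$clones_strict
  res_str <- purrr::map_chr(strict$assignments,
                            ~ if (is.null(.x)) NA_character_ else paste(.x, collapse = ""))
  m <- match(res_str, library$clones$residues)
  tested_id <- ifelse(is.na(m), res_str, library$clones$clone_id[m])
  tested_reactive <- !is.na(m) & library$clones$reactive[ifelse(is.na(m), 1L, m)]
  plate <- simulate_elisa(tested_id, tested_reactive,
                          n_negative = cfg$n_negative, n_positive = cfg$n_positive,
                          neg_mean = cfg$neg_mean, neg_sd = cfg$neg_sd,
                          seed = stage_seed(seed, 8L))
  elisa <- call_ar_clones(plate, k = cfg$elisa_k)

  loaded <- unique(unlist(occupancy$clone_ids))
  truth_ar <- library$clones$clone_id[library$clones$reactive &
                                        library$clones$clone_id %in% loaded]
  found_ar <- elisa$calls$clone_id[elisa$calls$ar_call]
  evaluation <- tibble(
    n_reactive_loaded = length(truth_ar),
    recall = if (length(truth_ar)) mean(truth_ar %in% found_ar) else NA_real_,
    precision = if (length(found_ar)) mean(found_ar %in% truth_ar) else NA_real_
  )

  funnel <- tibble(
    stage = c("wells_screened", "wells_occupied", "ar_hit_wells", "reads",
              "unique_clones", "clones_strict", "clones_relaxed",
              "ar_confirmed"),
    count = c(n_wells(layout), sum(occupancy$n_cells > 0), sum(hits$wells$hit),
              nrow(reads), nrow(ident$clones), nrow(ident$clones_strict),
              nrow(ident$clones_relaxed), elisa$n_ar)
  )
  manifest <- list(
    seed = seed,
    stage_seeds = setNames(stage_seed(seed, 1:8), paste0("stage_", 1:8)),
    config = lapply(unclass(cfg), function(x) if (inherits(x, "planar_transform")) {
      c(a11 = x$A[1, 1], a12 = x$A[1, 2], a21 = x$A[2, 1], a22 = x$A[2, 2],
        tx = x$t[1], ty = x$t[2])
    } else x),
    funnel = setNames(as.list(funnel$count), funnel$stage)
  )
  structure(
    list(layout = layout, library = library, occupancy = occupancy,
         truth = fl$truth, brightfield = sb, fluorescence = sf,
         measurements = meas, hits = hits, fit = fit, plan = plan,
         reads = reads, ident = ident, plate = plate, elisa = elisa,
         funnel = funnel, evaluation = evaluation, manifest = manifest),
    class = "screen_run"
  )
}

#' @export
print.screen_run <- function(x, ...) {
  cat("<screen_run>\n")
  print(funnel_report(x), n = Inf)
  invisible(x)
}

#' Hit ratio of a screening funnel stage
#'
#' @param n_hits,n_screened Stage counts.
#' @return The ratio as a percentage (e.g. 318 hits among 70,000 wells is
#'   ~0.45).
#' @examples
#' hit_ratio(318, 70000)
#' @export
hit_ratio <- function(n_hits, n_screened) {
  if (any(n_screened <= 0)) {
    ws_abort("`n_screened` must be positive.", "invalid_parameter")
  }
  100 * n_hits / n_screened
}

#' Human-readable screening funnel
#'
#' Counts at every pipeline stage, each with its percentage of the stage it
#' is conventionally reported against (hit wells per screened well; strict
#' and relaxed clones per unique clone; AR-confirmed per strict-tested
#' clone).
#'
#' @param run A [run_screen()] result (or its `manifest`).
#' @return A tibble `stage`, `count`, `percent_of`, `percent`.
#' @export
funnel_report <- function(run) {
  fun <- if (inherits(run, "screen_run")) {
    run$manifest$funnel
  } else if (is.list(run) && !is.null(run$funnel)) {
    run$funnel
  } else {
    ws_abort("`run` has no funnel; was the pipeline completed?", "missing_stage")
  }
  need <- c("wells_screened", "ar_hit_wells", "clones_strict", "ar_confirmed")
  if (!all(need %in% names(fun))) {
    ws_abort("Funnel is missing stages; was the pipeline completed?",
             "missing_stage")
  }
  cnt <- unlist(fun)
  ref <- c(wells_occupied = "wells_screened", ar_hit_wells = "wells_screened",
           clones_strict = "unique_clones", clones_relaxed = "unique_clones",
           ar_confirmed = "clones_strict")
  percent_of <- unname(ref[names(cnt)])
  denom <- ifelse(is.na(percent_of), NA_real_, cnt[percent_of])
  tibble(
    stage = names(cnt),
    count = unname(cnt),
    percent_of = percent_of,
    percent = unname(100 * cnt / denom)
  )
}

#' @export
tidy.screen_run <- function(x, ...) x$funnel

#' @export
glance.screen_run <- function(x, ...) {
  fun <- x$manifest$funnel
  tibble(
    wells_screened = fun$wells_screened,
    ar_hit_wells = fun$ar_hit_wells,
    hit_ratio_pct = hit_ratio(fun$ar_hit_wells, fun$wells_screened),
    unique_clones = fun$unique_clones,
    clones_strict = fun$clones_strict,
    ar_confirmed = fun$ar_confirmed,
    recall = x$evaluation$recall,
    precision = x$evaluation$precision
  )
}

#' @export
autoplot.screen_run <- function(object, ...) {
  d <- object$funnel
  d$stage <- factor(d$stage, levels = rev(d$stage))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$count, y = .data$stage)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "count (log scale)", y = NULL,
                  title = "Screening funnel") +
    ggplot2::theme_minimal()
}

#' Serialised run manifest
#'
#' Canonical JSON text of the manifest (config snapshot, seeds, funnel);
#' identical seeds and configs produce byte-identical manifests.
#'
#' @param run A [run_screen()] result.
#' @return A JSON string.
#' @export
manifest_json <- function(run) {
  stopifnot(inherits(run, "screen_run"))
  as.character(jsonlite::toJSON(run$manifest, auto_unbox = TRUE, digits = NA))
}

#' Write all tabular outputs of a run
#'
#' Writes `wells.tsv`, `retrieval_plan.tsv`, `clones.tsv`,
#' `filter_report.tsv`, `elisa_calls.tsv` and `manifest.json` under `dir`.
#'
#' @param run A [run_screen()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_screen_outputs <- function(run, dir) {
  stopifnot(inherits(run, "screen_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_screen_tsv(run$hits$wells, file.path(dir, "wells.tsv"))
  write_screen_tsv(run$plan, file.path(dir, "retrieval_plan.tsv"))
  write_screen_tsv(run$ident$clones[c("clone_key", "vl_aa", "vh_aa",
                                      "unintended", "read_count")],
                   file.path(dir, "clones.tsv"))
  write_screen_tsv(run$ident$report, file.path(dir, "filter_report.tsv"))
  write_screen_tsv(run$elisa$calls, file.path(dir, "elisa_calls.tsv"))
  writeLines(manifest_json(run), file.path(dir, "manifest.json"))
  invisible(dir)
}
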