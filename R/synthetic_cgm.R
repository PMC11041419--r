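# ---- archetypal fluctuation templates ---------------------------------------

# Template shape functions on s in [0, 1], mmol/L. These are the package's
# own constructions anchored to six pattern descriptions typical of T1DM
# (glucose level band + trend); they are fixtures with strictly increasing
# means, not reconstructions of any fitted centroid.
template_shapes <- list(
  function(s) 4.2 + 0.8 * (2 * s - 1)^2,         # 1: steady 3-6, concave up
  function(s) 6 + 2 * s,                         # 2: normal, slight rise 6->8
  function(s) 11 - 5 * s,                        # 3: declining 11->6
  function(s) 11 + 5 * s,                        # 4: rising 11->16
  function(s) 14 + 20 * s * (1 - s),             # 5: hyperglycemic 14-19, concave
  function(s) ifelse(s <= 0.4, 19 + 22.5 * s,    # 6: severe 19-28, peak & decline
                     28 - (7 / 0.6) * (s - 0.4))
)

#' The six archetypal glucose fluctuation templates
#'
#' Deterministic 15-minute-resolution value sequences emulating the six
#' fluctuation archetypes of T1DM CGM data: (1) steady marginally-hypoglycemic-to-normal
#' around 3-6 mmol/L, (2) normal with a slight rise 6-8, (3) declining from
#' marginally hyperglycemic to normal (~11 to 6), (4) rising from marginally
#' hyperglycemic to hyperglycemic (~11 to 16), (5) hyperglycemic 14-19 with
#' a concave bump, (6) severely hyperglycemic 19-28 rising to a peak and
#' declining. Template means increase strictly from 1 to 6.
#'
#' @param duration template length in minutes (>= 30).
#' @param interval sampling interval in minutes (default 15).
#' @return list of 6 numeric sequences of length `floor(duration/interval)`.
#' @export
pattern_templates <- function(duration = 150, interval = 15) {
  stopifnot(duration >= 30)
  n <- max(2L, as.integer(floor(duration / interval)))
  s <- (seq_len(n) - 1) / (n - 1)
  lapply(template_shapes, function(f) f(s))
}

#' Patient-cluster archetypes of time in patterns
#'
#' Mean time-in-patterns compositions (percent over the 6 templates) of the
#' four canonical glycemic-variability patient profiles, renormalized to sum
#' exactly to 100. Row A is the large mixed-hyperglycemia profile, B the
#' small severely hyperglycemic profile, C the in-target-but-variable
#' profile, D the well-controlled profile.
#'
#' @return a 4 x 6 matrix with rownames A-D.
#' @export
gv_archetypes <- function() {
  m <- rbind(
    A = c(13.6, 17.0, 22.4, 23.1, 19.3, 4.7),
    B = c(2.1, 3.6, 6.8, 10.1, 26.2, 51.2),
    C = c(27.6, 27.6, 23.5, 15.6, 5.5, 0.3),
    D = c(51.9, 32.5, 10.2, 5.0, 0.4, 0.0)
  )
  colnames(m) <- paste0("tip_", 1:6)
  100 * m / rowSums(m)
}

# ---- configuration ----------------------------------------------------------

#' Synthetic CGM cohort configuration
#'
#' States the world the generator emulates: nominal 15-minute flash-monitor
#' sampling, glucose roughly in 2-28 mmol/L (clipped to \[1, 30\]), sensor
#' dropouts, days tiled by contiguous template segments whose mixture per
#' patient follows one of the four cluster archetypes, overnight (2-6 AM)
#' enrichment of the steady low template and meal-hour (9 AM / 1 PM / 7 PM)
#' enrichment of the rising templates 2 and 4.
#'
#' @param n_patients number of patients (default 20).
#' @param days_per_patient days of wear per patient (default 14).
#' @param sampling_interval minutes between samples (default 15).
#' @param noise_sd i.i.d. Gaussian sensor noise, mmol/L (default 0.5).
#' @param dropout_rate fraction of samples removed at random (default 0.05).
#' @param segment_minutes template segment length; equal to the default
#'   window duration so ground truth is unambiguous at window granularity.
#' @param meal_hours clock hours with enriched rising patterns.
#' @param night_hours half-open clock-hour interval with enriched pattern 1.
#' @param meal_boost,night_boost multiplicative weight enrichments.
#' @param archetypes archetype composition matrix (rows sum to 100).
#' @param cluster_weights probability of each archetype per patient
#'   (defaults to prevalences 74/4/35/13 of 126, typical of a T1DM cohort:
#'   profile A common, the severe profile B rare).
#' @param dirichlet_precision concentration of per-patient mixtures around
#'   their archetype (default 60, giving within-profile component SDs of
#'   roughly 4-6 percentage points).
#' @param seed integer seed.
#' @param start first timestamp (midnight, UTC).
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 20, days_per_patient = 14,
                             sampling_interval = 15, noise_sd = 0.5,
                             dropout_rate = 0.05, segment_minutes = 150,
                             meal_hours = c(9, 13, 19), night_hours = c(2, 6),
                             meal_boost = 3, night_boost = 4,
                             archetypes = gv_archetypes(),
                             cluster_weights = c(74, 4, 35, 13) / 126,
                             dirichlet_precision = 60, seed = 1,
                             start = "2023-01-01") {
  stopifnot(n_patients >= 1, days_per_patient >= 1, sampling_interval >= 1,
            noise_sd >= 0, dropout_rate >= 0, dropout_rate < 1,
            segment_minutes >= 30)
  stopifnot(all(abs(rowSums(archetypes) - 100) < 1e-6), all(archetypes >= 0))
  cluster_weights <- cluster_weights / sum(cluster_weights)
  structure(as.list(environment()), class = "synthetic_config")
}

# ---- generation -------------------------------------------------------------

#' Generate a synthetic CGM cohort with known pattern structure
#'
#' Each patient draws an archetype, then a personal template mixture from a
#' Dirichlet around that archetype's composition. The wear period is tiled
#' with contiguous template segments; each segment's template is drawn from
#' the mixture after diurnal reweighting (overnight favors template 1,
#' meal hours favor templates 2 and 4). Gaussian noise is added, values are
#' clipped to \[1, 30\] mmol/L, and samples are dropped at the configured
#' rate. Fully reproducible from the seed.
#'
#' @param config a [synthetic_config()].
#' @return list with `data` (CGM tibble `patient_id`, `time`, `glucose`),
#'   `truth` (tibble `patient_id`, `segment_start`, `segment_index`,
#'   `template`, `archetype`), `mixtures` (per-patient drawn template
#'   mixture, percent), and `config`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  t0 <- as.POSIXct(paste(cfg$start, "00:00:00"), tz = "UTC")
  seg <- cfg$segment_minutes
  n_seg <- floor(cfg$days_per_patient * 1440 / seg)
  n_per_seg <- floor(seg / cfg$sampling_interval)
  templ <- pattern_templates(seg, cfg$sampling_interval)
  arch_names <- rownames(cfg$archetypes)
  with_seed(cfg$seed, {
    data_rows <- vector("list", cfg$n_patients)
    truth_rows <- vector("list", cfg$n_patients)
    mixtures <- matrix(NA_real_, cfg$n_patients, ncol(cfg$archetypes))
    pids <- sprintf("P%03d", seq_len(cfg$n_patients))
    archetype <- arch_names[sample.int(length(arch_names), cfg$n_patients,
                                       replace = TRUE,
                                       prob = cfg$cluster_weights)]
    for (i in seq_len(cfg$n_patients)) {
      # zero archetype shares stay exactly zero (gamma with shape 0 is 0),
      # so one-hot archetypes generate deterministic mixtures
      alpha <- cfg$archetypes[archetype[i], ] / 100 * cfg$dirichlet_precision
      w0 <- as.numeric(rdirichlet(1, alpha))
      mixtures[i, ] <- 100 * w0
      seg_starts <- (seq_len(n_seg) - 1) * seg
      mid_hour <- ((seg_starts + seg / 2) / 60) %% 24
      tids <- integer(n_seg)
      for (j in seq_len(n_seg)) {
        w <- w0
        if (mid_hour[j] >= cfg$night_hours[1] && mid_hour[j] < cfg$night_hours[2])
          w[1] <- w[1] * cfg$night_boost
        # a clock hour h falls inside segment j iff (h*60 - start) mod 1440 < seg
        meal_in_seg <- ((cfg$meal_hours * 60 - seg_starts[j]) %% 1440) < seg
        if (any(meal_in_seg)) {
          w[2] <- w[2] * cfg$meal_boost
          w[4] <- w[4] * cfg$meal_boost
        }
        tids[j] <- sample.int(6, 1, prob = w / sum(w))
      }
      offsets <- as.vector(outer((seq_len(n_per_seg) - 1) * cfg$sampling_interval,
                                 seg_starts, "+"))
      values <- as.vector(vapply(tids, function(t) templ[[t]],
                                 numeric(n_per_seg)))
      if (cfg$noise_sd > 0)
        values <- values + stats::rnorm(length(values), 0, cfg$noise_sd)
      values <- pmin(pmax(values, 1), 30)
      keep <- if (cfg$dropout_rate > 0)
        stats::runif(length(values)) >= cfg$dropout_rate else
        rep(TRUE, length(values))
      data_rows[[i]] <- tibble::tibble(
        patient_id = pids[i],
        time = t0 + offsets[keep] * 60,
        glucose = values[keep]
      )
      truth_rows[[i]] <- tibble::tibble(
        patient_id = pids[i],
        segment_start = t0 + seg_starts * 60,
        segment_index = seq_len(n_seg),
        template = tids,
        archetype = archetype[i]
      )
    }
  })
  rownames(mixtures) <- pids
  colnames(mixtures) <- paste0("tip_", seq_len(ncol(mixtures)))
  list(data = dplyr::bind_rows(data_rows),
       truth = dplyr::bind_rows(truth_rows),
       mixtures = mixtures, config = cfg)
}

#' Simulate standalone pattern windows with known labels
#'
#' Draws `n` windows directly from the six templates (chosen by `weights`)
#' plus i.i.d. Gaussian noise — the planted-structure fixture for clustering
#' checks, bypassing trace generation and windowing.
#'
#' @param n number of windows.
#' @param duration window duration in minutes (default 150).
#' @param noise_sd Gaussian noise SD in mmol/L (default 0.5).
#' @param weights template mixture (default uniform over the 6).
#' @param seed integer seed.
#' @param interval sampling interval (default 15).
#' @return list with `values` (list of numeric sequences) and `truth`
#'   (integer template per window).
#' @export
simulate_pattern_windows <- function(n, duration = 150, noise_sd = 0.5,
                                     weights = rep(1 / 6, 6), seed = 1,
                                     interval = 15) {
  templ <- pattern_templates(duration, interval)
  with_seed(seed, {
    truth <- sample.int(6, n, replace = TRUE, prob = weights)
    values <- lapply(truth, function(t) {
      v <- templ[[t]] + stats::rnorm(length(templ[[t]]), 0, noise_sd)
      pmin(pmax(v, 1), 30)
    })
  })
  list(values = values, truth = truth)
}

#' Simulate time-in-patterns compositions from the cluster archetypes
#'
#' Draws per-patient compositions from Dirichlet distributions centred on
#' each archetype row — the planted-structure fixture for the patient
#' clustering stage.
#'
#' @param n_per_cluster patients per archetype (scalar or vector matching
#'   the archetype rows).
#' @param archetypes composition matrix (rows sum to 100).
#' @param precision Dirichlet concentration (default 60).
#' @param seed integer seed.
#' @return tibble with `patient_id`, `archetype`, `n_windows` (nominal),
#'   and `tip_*` percentage columns summing to 100.
#' @export
simulate_compositions <- function(n_per_cluster = 15,
                                  archetypes = gv_archetypes(),
                                  precision = 60, seed = 1) {
  kA <- nrow(archetypes)
  n_per <- rep_len(n_per_cluster, kA)
  with_seed(seed, {
    rows <- lapply(seq_len(kA), function(a) {
      alpha <- archetypes[a, ] / 100 * precision
      comp <- 100 * rdirichlet(n_per[a], alpha)
      out <- tibble::tibble(
        patient_id = sprintf("%s%02d", rownames(archetypes)[a], seq_len(n_per[a])),
        archetype = rownames(archetypes)[a], n_windows = NA_integer_)
      out[colnames(archetypes)] <- as.data.frame(comp)
      out
    })
    dplyr::bind_rows(rows)
  })
}

#' Majority-template ground truth for extracted windows
#'
#' Maps each extracted window back to the generator's segment truth: the
#' window's label is the template covering the strict majority of its
#' samples, `NA` when no template does (e.g. a 50/50 straddle of a segment
#' boundary, which has no single true label).
#'
#' @param windows window tibble from [extract_windows()].
#' @param truth `truth` tibble from [generate_cohort()].
#' @param segment_minutes segment length used at generation.
#' @return integer template label (or `NA`) per window.
#' @export
window_ground_truth <- function(windows, truth, segment_minutes = 150) {
  tr <- split(truth, truth$patient_id)
  vapply(seq_len(nrow(windows)), function(i) {
    ti <- tr[[windows$patient_id[i]]]
    t0 <- min(ti$segment_start)
    times <- as.numeric(difftime(windows$start[i], t0, units = "mins")) +
      windows$offsets[[i]]
    seg_idx <- floor(times / segment_minutes) + 1
    ok <- seg_idx >= 1 & seg_idx <= nrow(ti)
    if (!any(ok)) return(NA_integer_)
    tmpl <- ti$template[seg_idx[ok]]
    tab <- table(tmpl)
    top <- which(tab == max(tab))
    if (length(top) > 1 || max(tab) <= length(tmpl) / 2) return(NA_integer_)
    as.integer(names(tab)[top])
  }, 1L)
}
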