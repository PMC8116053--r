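# CSV dialect: comma-separated, dot decimal, UTF-8, header required. Reals are
# written with 17 significant digits so write -> read round-trips exactly.

.fmt_real <- function(x) {
  out <- vapply(x, function(v) sprintf("%.17g", v), character(1L))
  out
}

.write_csv17 <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- .fmt_real(out[[nm]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Read EPSC sweep tables
#'
#' Reads a long-format CSV with header `pair_id, sweep, pulse_index,
#' amplitude_pA` and optional `baseline_pA`, and returns one dense
#' [sweep_matrix()] per pair. `pulse_index` is 1-based and must form a
#' complete sweeps x pulses grid per pair; duplicates or missing cells are
#' errors naming the offending rows.
#'
#' @param path CSV file path.
#' @param apply_baseline apply [baseline_correct()] when a `baseline_pA`
#'   column is present (default TRUE).
#' @return named list of [sweep_matrix()], one per `pair_id`.
#' @export
read_sweeps <- function(path, apply_baseline = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "sweep", "pulse_index", "amplitude_pA")
  if (!all(need %in% names(df))) {
    stop("sweep CSV must have columns: ", paste(need, collapse = ", "))
  }
  has_base <- "baseline_pA" %in% names(df)
  key <- paste(df$pair_id, df$sweep, df$pulse_index)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf(
      "duplicate (pair, sweep, pulse) at data row %d: %s", dup[1L], key[dup[1L]]
    ))
  }
  if (anyNA(df$amplitude_pA)) {
    stop(sprintf("missing amplitude at data row %d", which(is.na(df$amplitude_pA))[1L]))
  }
  out <- list()
  for (pid in unique(df$pair_id)) {
    d <- df[df$pair_id == pid, , drop = FALSE]
    sweeps <- sort(unique(d$sweep))
    pulses <- sort(unique(d$pulse_index))
    if (!identical(as.integer(pulses), seq_along(pulses))) {
      stop(sprintf("pair '%s': pulse_index must be contiguous starting at 1", pid))
    }
    if (nrow(d) != length(sweeps) * length(pulses)) {
      stop(sprintf("pair '%s': ragged sweeps (incomplete sweep x pulse grid)", pid))
    }
    m <- matrix(NA_real_, length(sweeps), length(pulses))
    rows <- match(d$sweep, sweeps)
    m[cbind(rows, d$pulse_index)] <- d$amplitude_pA
    if (anyNA(m)) stop(sprintf("pair '%s': missing cells in sweep grid", pid))
    if (has_base && apply_baseline) {
      b <- matrix(NA_real_, length(sweeps), length(pulses))
      b[cbind(rows, d$pulse_index)] <- d$baseline_pA
      out[[as.character(pid)]] <- baseline_correct(m, b)
    } else {
      out[[as.character(pid)]] <- sweep_matrix(m, baseline_corrected = FALSE)
    }
  }
  out
}

#' Write EPSC sweep tables
#'
#' Inverse of [read_sweeps()] (amplitudes written as already corrected; no
#' baseline column is emitted). Reals carry 17 significant digits.
#'
#' @param sweeps named list of [sweep_matrix()] objects.
#' @param path output CSV path.
#' @export
write_sweeps <- function(sweeps, path) {
  if (inherits(sweeps, "sweep_matrix")) sweeps <- list(pair1 = sweeps)
  rows <- lapply(names(sweeps), function(pid) {
    sw <- sweeps[[pid]]
    grid <- expand.grid(
      sweep = seq_len(sw$n_sweeps), pulse_index = seq_len(sw$n_pulses)
    )
    data.frame(
      pair_id = pid, sweep = grid$sweep, pulse_index = grid$pulse_index,
      amplitude_pA = sw$amplitudes_pA[cbind(grid$sweep, grid$pulse_index)]
    )
  })
  .write_csv17(do.call(rbind, rows), path)
  invisible(path)
}

#' Read gold-particle point patterns with their AZ polygons
#'
#' Points CSV: `az_id, x_nm, y_nm`. Polygons CSV: `az_id, vertex_index, x_nm,
#' y_nm` with 1-based, counterclockwise vertex ordering. Polygons are
#' validated for simplicity, and every point must lie inside or on its
#' polygon (closed convention); violations are errors naming the AZ and
#' coordinates. AZs with zero points are permitted.
#'
#' @param points_path,polygons_path CSV file paths.
#' @return named list of [point_pattern()] objects, one per AZ.
#' @export
read_patterns <- function(points_path, polygons_path) {
  pts <- read.csv(points_path, stringsAsFactors = FALSE)
  pol <- read.csv(polygons_path, stringsAsFactors = FALSE)
  if (!all(c("az_id", "x_nm", "y_nm") %in% names(pts))) {
    stop("points CSV must have columns az_id, x_nm, y_nm")
  }
  if (!all(c("az_id", "vertex_index", "x_nm", "y_nm") %in% names(pol))) {
    stop("polygons CSV must have columns az_id, vertex_index, x_nm, y_nm")
  }
  az_ids <- unique(pol$az_id)
  orphan <- setdiff(unique(pts$az_id), az_ids)
  if (length(orphan)) {
    stop("points reference az_id with no polygon: ", paste(orphan, collapse = ", "))
  }
  out <- list()
  for (id in az_ids) {
    pv <- pol[pol$az_id == id, , drop = FALSE]
    pv <- pv[order(pv$vertex_index), , drop = FALSE]
    poly <- az_polygon(cbind(pv$x_nm, pv$y_nm))
    pp <- pts[pts$az_id == id, c("x_nm", "y_nm"), drop = FALSE]
    out[[as.character(id)]] <- point_pattern(as.matrix(pp), poly, az_id = id)
  }
  out
}

#' Write point patterns and their polygons
#'
#' Inverse of [read_patterns()].
#'
#' @param patterns list of [point_pattern()] objects.
#' @param points_path,polygons_path output CSV paths.
#' @export
write_patterns <- function(patterns, points_path, polygons_path) {
  if (inherits(patterns, "point_pattern")) patterns <- list(patterns)
  pts <- do.call(rbind, lapply(patterns, function(p) {
    if (p$n_points == 0L) return(NULL)
    data.frame(az_id = p$az_id, x_nm = p$points_nm[, 1L], y_nm = p$points_nm[, 2L])
  }))
  if (is.null(pts)) {
    pts <- data.frame(az_id = character(0), x_nm = numeric(0), y_nm = numeric(0))
  }
  pol <- do.call(rbind, lapply(patterns, function(p) {
    v <- p$polygon$vertices_nm
    data.frame(
      az_id = p$az_id, vertex_index = seq_len(nrow(v)),
      x_nm = v[, 1L], y_nm = v[, 2L]
    )
  }))
  .write_csv17(pts, points_path)
  .write_csv17(pol, polygons_path)
  invisible(c(points_path, polygons_path))
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values are parsed
#' as numeric vectors (comma-separated), logicals, or left as strings.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) {
      num
    } else if (all(tolower(parts) %in% c("true", "false"))) {
      tolower(parts) == "true"
    } else {
      if (length(parts) == 1L) val else parts
    }
  }
  out
}

# Deterministic per-stage seed derived from the run seed and a stage tag.
.stage_seed <- function(seed, tag) {
  offsets <- c(
    simulate = 101L, mpfa = 211L, spatial = 307L,
    labeling = 401L, intensity = 503L
  )
  (as.integer(seed) * 97L + offsets[[tag]]) %% 2147483647L
}

.default_config <- function() {
  list(
    seed = 1, out_dir = ".",
    stages = c("simulate", "mpfa", "spatial", "labeling", "intensity"),
    # quantal generator (binomial release model)
    n_pairs = 10, n_sweeps = 30, n_sites = 10, q_pA = 30,
    pv_per_pulse = c(0.8, 0.65, 0.5, 0.4, 0.3, 0.2),
    cv_q = 0, noise_sd_pA = 2,
    min_sweeps = 24, sweep_rule = "warn",
    # AZ generator (measured population geometry)
    n_az = 10, az_area_um2 = 0.071, az_vertices = 8, az_irregularity = 0.25,
    points_per_az = 26, pattern_mode = "clustered", n_clusters = 5,
    sigma_nm = 15,
    # spatial analysis
    nnd_reps = 200, mad_sims = 200, eps_min = 1, eps_max = 100, min_pts = 2,
    eps_null = 20,
    # labeling model
    label_p = 0.5, label_n_ep = 80, label_n_synapses = 10000,
    observed_cv = 0.33,
    # intensity
    n_synapses = 200, munc13_density_cv = 0.33
  )
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the selected stages in order - `simulate` (write generator CSVs),
#' `mpfa` (per-pair quantal fits), `spatial` (per-AZ NND / MAD / DBSCAN
#' report), `labeling` (binomial labeling model), `intensity` (normalized
#' intensities and correlations) - reading its inputs from `out_dir`, writing
#' one CSV per stage plus a `manifest.json` recording parameters, derived
#' stage seeds, package version and row counts. Identical config and seed
#' give byte-identical numeric outputs. A stage failure is recorded in the
#' manifest and downstream stages are skipped.
#'
#' @param config named list overriding the defaults, or the path of a
#'   `key = value` config file (see [read_config()]). Keys include `seed`,
#'   `out_dir`, `stages`, and per-stage parameters.
#' @return (invisibly) list with `ok`, `manifest`, `files`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_config(config)
  cfg <- utils::modifyList(.default_config(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  manifest <- list(
    package = "azquant",
    version = as.character(packageVersion("azquant")),
    seed = cfg$seed,
    stages = cfg$stages,
    parameters = cfg[setdiff(names(cfg), c("stages", "out_dir"))],
    stage_seeds = lapply(
      stats::setNames(nm = cfg$stages),
      function(s) .stage_seed(cfg$seed, s)
    ),
    results = list(),
    error = NULL
  )
  ok <- TRUE
  for (stage in cfg$stages) {
    message(sprintf("[azquant] stage %s", stage))
    res <- tryCatch(
      .run_stage(stage, cfg),
      error = function(e) structure(list(message = conditionMessage(e)), class = "stage_error")
    )
    if (inherits(res, "stage_error")) {
      manifest$error <- list(stage = stage, message = res$message)
      message(sprintf("[azquant] stage %s FAILED: %s; skipping downstream stages",
                      stage, res$message))
      ok <- FALSE
      break
    }
    manifest$results[[stage]] <- res$info
    files <- c(files, res$files)
  }
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(ok = ok, manifest = manifest, files = c(files, manifest_path)))
}

.run_stage <- function(stage, cfg) {
  seed <- .stage_seed(cfg$seed, stage)
  out <- function(name) file.path(cfg$out_dir, name)
  switch(stage,
    simulate = {
      truth <- quantal_ground_truth(
        cfg$n_sites, cfg$q_pA, cfg$pv_per_pulse, cfg$cv_q, cfg$noise_sd_pA
      )
      sweeps <- lapply(seq_len(cfg$n_pairs), function(i) {
        gen_quantal_sweeps(truth, cfg$n_sweeps, seed = seed + i)
      })
      names(sweeps) <- sprintf("pair%03d", seq_len(cfg$n_pairs))
      write_sweeps(sweeps, out("sweeps.csv"))
      patterns <- lapply(seq_len(cfg$n_az), function(i) {
        poly <- gen_az_polygon(
          cfg$az_area_um2, cfg$az_vertices, cfg$az_irregularity,
          seed = seed + 1000L + i
        )
        gen_point_pattern(
          poly, mode = cfg$pattern_mode, n_points = cfg$points_per_az,
          n_clusters = cfg$n_clusters, sigma_nm = cfg$sigma_nm,
          seed = seed + 2000L + i, az_id = sprintf("AZ%03d", i)
        )
      })
      write_patterns(patterns, out("points.csv"), out("polygons.csv"))
      syn <- gen_synapse_population(
        cfg$n_synapses, munc13_density_cv = cfg$munc13_density_cv,
        seed = seed + 3000L
      )
      .write_csv17(syn, out("synapses.csv"))
      list(
        info = list(n_pairs = cfg$n_pairs, n_az = cfg$n_az,
                    n_synapses = cfg$n_synapses),
        files = c(out("sweeps.csv"), out("points.csv"), out("polygons.csv"),
                  out("synapses.csv"))
      )
    },
    mpfa = {
      sweeps <- read_sweeps(out("sweeps.csv"))
      rows <- lapply(names(sweeps), function(pid) {
        sw <- sweeps[[pid]]
        if (cfg$sweep_rule == "drop" && sw$n_sweeps < cfg$min_sweeps) {
          return(NULL)
        }
        mv <- suppressWarnings(mean_variance(sw, min_sweeps = cfg$min_sweeps))
        fit <- mpfa_fit(mv)
        data.frame(
          pair_id = pid, n_points = fit$n_points,
          n_hat = fit$n_hat, q_hat_pA = fit$q_hat_pA, pv1 = fit$pv1,
          qc_excluded = fit$qc_excluded, fit_ok = fit$fit_ok, rss = fit$rss,
          ppr = paired_pulse_ratio(sw)
        )
      })
      res <- do.call(rbind, rows)
      .write_csv17(res, out("mpfa_results.csv"))
      list(info = list(n_pairs = nrow(res)), files = out("mpfa_results.csv"))
    },
    spatial = {
      patterns <- read_patterns(out("points.csv"), out("polygons.csv"))
      rows <- lapply(patterns, function(p) {
        base <- data.frame(
          az_id = p$az_id, n_points = p$n_points,
          area_um2 = p$polygon$area_um2,
          mean_nnd_nm = NA_real_, null_nnd_nm = NA_real_, mad_p = NA_real_,
          clustered = NA, n_clusters = NA_integer_,
          cluster_density_per_um2 = NA_real_,
          mean_particles_per_cluster = NA_real_,
          intercluster_nnd_nm = NA_real_,
          gold_density_per_um2 = gold_density(p)
        )
        if (p$n_points >= 2L) {
          nnd <- csr_null_nnd(p, n_reps = cfg$nnd_reps, seed = seed + 1L)
          base$mean_nnd_nm <- nnd$observed_nnd_nm
          base$null_nnd_nm <- nnd$null_nnd_nm
        }
        if (p$n_points >= 5L) {
          mt <- mad_test(p, n_sim = cfg$mad_sims, seed = seed + 2L)
          base$mad_p <- mt$mad_p
          base$clustered <- mt$clustered
          # clusters are only identified in AZs compatible with clustering
          if (mt$clustered) {
            es <- eps_sweep(
              list(p), eps_range_nm = c(cfg$eps_min, cfg$eps_max),
              min_pts = cfg$min_pts, n_null = cfg$eps_null, seed = seed + 3L
            )
            cl <- dbscan(p$points_nm, es$eps_star, cfg$min_pts)
            met <- cluster_metrics(cl, p$polygon)
            base$n_clusters <- met$n_clusters
            base$cluster_density_per_um2 <- met$cluster_density_per_um2
            base$mean_particles_per_cluster <- met$mean_particles_per_cluster
            base$intercluster_nnd_nm <- met$mean_intercluster_nnd_nm
          }
        }
        base
      })
      res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
      .write_csv17(res, out("spatial_results.csv"))
      list(info = list(n_az = nrow(res)), files = out("spatial_results.csv"))
    },
    labeling = {
      model <- labeling_model(cfg$label_p, cfg$label_n_ep)
      ana <- binomial_cv(model)
      sim <- simulate_labeling(model, cfg$label_n_synapses, seed = seed)
      res <- data.frame(
        p = cfg$label_p, n_ep = cfg$label_n_ep,
        mean_analytic = ana$mean, sd_analytic = ana$sd, cv_analytic = ana$cv,
        mean_sim = sim$mean, sd_sim = sim$sd, cv_sim = sim$cv,
        variance_fraction = labeling_variance_fraction(ana$cv, cfg$observed_cv),
        observed_cv = cfg$observed_cv
      )
      .write_csv17(res, out("labeling_results.csv"))
      list(info = list(cv_analytic = ana$cv), files = out("labeling_results.csv"))
    },
    intensity = {
      syn <- read.csv(out("synapses.csv"), stringsAsFactors = FALSE)
      norm_psd <- normalize_to_population(syn$psd95_intensity, syn$psd95_intensity)
      norm_munc <- normalize_to_population(syn$munc13_intensity, syn$munc13_intensity)
      rc <- ratio_cv(syn$munc13_intensity, syn$psd95_intensity)
      res <- data.frame(
        synapse_id = syn$synapse_id, area_um2 = syn$area_um2,
        psd95_relative = norm_psd$relative, munc13_relative = norm_munc$relative,
        munc13_psd95_ratio = rc$ratios
      )
      .write_csv17(res, out("intensity_normalized.csv"))
      pairs <- list(
        c("area_um2", "psd95_intensity"),
        c("area_um2", "munc13_intensity"),
        c("psd95_intensity", "munc13_intensity")
      )
      cors <- lapply(pairs, function(pr) {
        sp <- spearman_rs(syn[[pr[1L]]], syn[[pr[2L]]])
        data.frame(x = pr[1L], y = pr[2L], rs = sp$rs, p_raw = sp$p)
      })
      rep <- do.call(rbind, cors)
      rep$p_holm <- holm_bonferroni(rep$p_raw)
      rep$ratio_cv <- rc$cv
      .write_csv17(rep, out("intensity_correlations.csv"))
      list(
        info = list(n_synapses = nrow(res), ratio_cv = rc$cv),
        files = c(out("intensity_normalized.csv"), out("intensity_correlations.csv"))
      )
    },
    stop("unknown stage: ", stage)
  )
}
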