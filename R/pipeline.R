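# End-to-end experiment orchestration: generate the phantom and cases,
# simulate every user x case x region x method x phantom-variant trial,
# run registration -> planToReal -> MOD, and summarise.

#' Experiment configuration
#'
#' Describes the simulated bench experiment: four users placing the six
#' paired guides with three guidance methods on two phantom variants.
#'
#' @param master_seed integer; every random quantity in the experiment
#'   derives from it.
#' @param n_users number of simulated users (default 4).
#' @param methods subset of `"freehand"`, `"smartphone"`, `"hololens"`.
#' @param phantoms subset of `"conventional"`, `"realistic"`.
#' @param models named list of [placement_model()]s, one per method.
#' @param pointer_sigma_mm pointer noise for pinhole measurement
#'   (default 0.2 mm).
#' @param registration_sigma_mm noise on registration landmark/surface
#'   points (default 0: the navigation-side registration is the
#'   low-noise step of the protocol).
#' @param spacing_mm cross-section resampling step (default 0.1 mm).
#' @param tissue_thickness_mm silicone-analog thickness used for the
#'   realistic variant (default 2 mm).
#' @param phantom a [phantom_spec()]; defaults to one seeded from
#'   `master_seed`.
#' @param n_landmarks,n_surface_points registration point counts
#'   (defaults 6 and 40).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(master_seed = 1L, n_users = 4L,
                              methods = c("freehand", "smartphone", "hololens"),
                              phantoms = c("conventional", "realistic"),
                              models = default_placement_models(),
                              pointer_sigma_mm = 0.2,
                              registration_sigma_mm = 0,
                              spacing_mm = 0.1,
                              tissue_thickness_mm = 2,
                              phantom = NULL,
                              n_landmarks = 6L, n_surface_points = 40L) {
  if (n_users < 1) stop("config$n_users must be >= 1")
  if (length(methods) < 1) stop("config$methods must be non-empty")
  bad <- setdiff(methods, c("freehand", "smartphone", "hololens"))
  if (length(bad)) stop("config$methods: unknown method ", bad[1])
  bad <- setdiff(phantoms, c("conventional", "realistic"))
  if (length(bad)) stop("config$phantoms: unknown variant ", bad[1])
  miss <- setdiff(methods, names(models))
  if (length(miss)) stop("config$models: no placement model for ", miss[1])
  for (m in methods)
    if (!inherits(models[[m]], "placement_model"))
      stop("config$models$", m, " is not a placement_model")
  if (pointer_sigma_mm < 0) stop("config$pointer_sigma_mm must be >= 0")
  if (spacing_mm <= 0) stop("config$spacing_mm must be > 0")
  if (tissue_thickness_mm < 0) stop("config$tissue_thickness_mm must be >= 0")
  if (n_landmarks < 3) stop("config$n_landmarks must be >= 3")
  if (n_surface_points < 3) stop("config$n_surface_points must be >= 3")
  structure(list(master_seed = as.integer(master_seed),
                 n_users = as.integer(n_users), methods = methods,
                 phantoms = phantoms, models = models,
                 pointer_sigma_mm = pointer_sigma_mm,
                 registration_sigma_mm = registration_sigma_mm,
                 spacing_mm = spacing_mm,
                 tissue_thickness_mm = tissue_thickness_mm,
                 phantom = phantom %||% phantom_spec(seed = master_seed),
                 n_landmarks = as.integer(n_landmarks),
                 n_surface_points = as.integer(n_surface_points)),
            class = "experiment_config")
}

#' Read or write an experiment configuration file
#'
#' Serialises the master seed and every model parameter of an
#' [experiment_config()] to a single JSON (or YAML, by extension
#' `.yaml`/`.yml`, requiring the yaml package) file, and back.
#'
#' @param config an `experiment_config`.
#' @param path config file path.
#' @return `read_experiment_config` returns an `experiment_config`;
#'   `write_experiment_config` returns `path` invisibly.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  obj <- unclass(config)
  obj$models <- lapply(obj$models, unclass)
  obj$phantom <- unclass(obj$phantom)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML config files")
    writeLines(yaml::as.yaml(obj), path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML config files")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  models <- lapply(obj$models, function(m)
    placement_model(m$method, m$rot_sigma_deg, m$trans_sigma_mm,
                    m$slip_prob, m$slip_scale_mm, m$tissue_extra_sigma_mm))
  phantom <- do.call(phantom_spec, obj$phantom)
  experiment_config(master_seed = obj$master_seed, n_users = obj$n_users,
                    methods = obj$methods, phantoms = obj$phantoms,
                    models = models,
                    pointer_sigma_mm = obj$pointer_sigma_mm,
                    registration_sigma_mm = obj$registration_sigma_mm,
                    spacing_mm = obj$spacing_mm,
                    tissue_thickness_mm = obj$tissue_thickness_mm,
                    phantom = phantom, n_landmarks = obj$n_landmarks,
                    n_surface_points = obj$n_surface_points)
}

# Per-trial seed stream: a deterministic counter hash of the master
# seed, independent across cells, always below 2^31.
derive_seed <- function(master_seed, index) {
  as.integer(((master_seed %% 1000003) * 1009 + index * 9973) %% 2147483629 + 1)
}

#' Simulate the bone-to-tracker reference pose and register it back
#'
#' Draws a ground-truth bone-to-tracker transform, simulates recording
#' landmarks and surface points with the tracked pointer, and recovers
#' the tracker-to-bone mapping by paired-point registration refined
#' with ICP, exactly once per phantom variant (the physical protocol
#' registers once, before coating).
#'
#' @param mesh bone `triangle_mesh`.
#' @param seed integer seed.
#' @param n_landmarks,n_surface_points point counts.
#' @param noise_sigma_mm measurement noise on the recorded points.
#' @return List with `truth` (bone-to-tracker `rigid_transform`),
#'   `paired` and `icp` `registration_result`s; `icp$transform` maps
#'   tracker to bone.
#' @export
simulate_registration <- function(mesh, seed, n_landmarks = 6L,
                                  n_surface_points = 40L,
                                  noise_sigma_mm = 0) {
  with_seed(seed, {
    truth <- rigid_transform(
      rotation_about_axis(rnorm(3), runif(1, 5, 15)),
      runif(3, -50, 50))
    lm_bone <- sample_surface_points(mesh, n_landmarks)
    sp_bone <- sample_surface_points(mesh, n_surface_points)
    lm_trk <- apply_transform(truth, lm_bone) +
      matrix(rnorm(3 * n_landmarks, 0, noise_sigma_mm), ncol = 3)
    sp_trk <- apply_transform(truth, sp_bone) +
      matrix(rnorm(3 * n_surface_points, 0, noise_sigma_mm), ncol = 3)
    paired <- paired_point_registration(lm_trk, lm_bone)
    icp <- icp_refine(sp_trk, mesh, init = paired$transform)
    list(truth = truth, paired = paired, icp = icp)
  })
}

# One placement trial, fully determined by its seed: draw the true
# placement, measure the pinholes with the pointer (tracker frame, then
# back through the estimated registration), estimate planToReal and
# score the achieved osteotomy.
.simulate_trial <- function(mesh, cs, model, tissue, T_bt, T_hat, config,
                            seed, planned_section) {
  with_seed(seed, {
    placement <- simulate_placement(cs, model, tissue)
    meas <- simulate_pinhole_measurement(cs, placement,
                                         config$pointer_sigma_mm)
    p_hat <- apply_transform(T_hat, apply_transform(T_bt, meas$points))
    p2r <- plan_to_real(cs$pinholes_planned,
                        fiducial_set(p_hat, meas$labels, "bone"))
    dev <- assess_placement(mesh, cs$plane, p2r$transform,
                            spacing = config$spacing_mm, region = cs$region,
                            planned_section = planned_section)
    list(dev = dev, rms = p2r$rms_residual, placement = placement)
  })
}

#' Run the full simulated placement-accuracy experiment
#'
#' Generates the phantom and the six paired cases, performs the bone
#' registration once per phantom variant, then for every
#' user x case x region x method cell simulates a guide placement,
#' measures the four pinholes with the tracked pointer (mapped through
#' the estimated registration), estimates planToReal, and computes the
#' maximum osteotomy deviation of the achieved cut. Deviations are then
#' summarised per phantom/method/region and compared with
#' Kruskal-Wallis and Dunn tests. Fully reproducible from
#' `config$master_seed`.
#'
#' @param config an [experiment_config()].
#' @return An object of class `psi_experiment` with elements `trials`
#'   (tidy data frame: case_id, region, method, phantom, user, seed,
#'   mod_mm, rms_pinhole_mm, status), `summary` (a [mod_report()]),
#'   `stats` (KW/Dunn results), `registrations`, `cases`, `mesh` and
#'   `config`.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  mesh <- make_phantom_mesh(config$phantom)
  cases <- make_cases(mesh, seed = config$master_seed)

  # planned sections are trial-invariant: compute once per case/region
  planned <- list()
  for (k in seq_along(cases)) for (r in c("S", "C")) {
    cs <- cases[[k]][[r]]
    planned[[paste(k, r)]] <- intersect_plane_mesh(mesh, cs$plane,
                                                   config$spacing_mm)
  }

  regs <- list()
  rows <- vector("list", 0)
  counter <- 0L
  for (pv in seq_along(config$phantoms)) {
    variant <- config$phantoms[pv]
    tissue <- if (variant == "realistic") config$tissue_thickness_mm else 0
    reg <- simulate_registration(mesh, derive_seed(config$master_seed, 900000 + pv),
                                 config$n_landmarks, config$n_surface_points,
                                 config$registration_sigma_mm)
    regs[[variant]] <- reg
    T_bt <- reg$truth                 # bone -> tracker (ground truth)
    T_hat <- reg$icp$transform        # tracker -> bone (estimated)
    for (user in seq_len(config$n_users))
      for (k in seq_along(cases))
        for (r in c("S", "C"))
          for (m in config$methods) {
            counter <- counter + 1L
            sd <- derive_seed(config$master_seed, counter)
            cs <- cases[[k]][[r]]
            res <- .simulate_trial(mesh, cs, config$models[[m]], tissue,
                                   T_bt, T_hat, config, sd,
                                   planned[[paste(k, r)]])
            rows[[counter]] <- data.frame(
              case_id = k, region = r, method = m, phantom = variant,
              user = user, seed = sd,
              mod_mm = res$dev$mod, rms_pinhole_mm = res$rms,
              status = res$dev$status, stringsAsFactors = FALSE)
          }
  }
  trials <- do.call(rbind, rows)
  out <- structure(list(trials = trials, summary = mod_report(trials),
                        stats = trial_stats(trials), registrations = regs,
                        cases = cases, mesh = mesh, config = config),
                   class = "psi_experiment")
  out
}

#' Deviation summary table per phantom, method and region
#'
#' Five-number summaries of the MOD values for each phantom variant and
#' guidance method, split by region (C, S) and pooled (Total) - the
#' standard bench-report layout. Off-bone placements are excluded from
#' the order statistics and tallied separately.
#'
#' @param trials tidy trial data frame as returned in
#'   `run_experiment()$trials`.
#' @return A data frame of class `mod_report` with columns `phantom`,
#'   `method`, `column` (C/S/Total), `n`, `min`, `q25`, `median`,
#'   `q75`, `max`, and attribute `off_bone` (count).
#' @export
mod_report <- function(trials) {
  if (!is.data.frame(trials) || nrow(trials) == 0)
    stop("trials must be a non-empty data frame")
  need <- c("region", "method", "phantom", "mod_mm", "status")
  if (!all(need %in% names(trials)))
    stop("trials must have columns ", paste(need, collapse = ", "))
  ok <- trials[trials$status == "ok", , drop = FALSE]
  rows <- list()
  for (pv in unique(trials$phantom))
    for (m in unique(trials$method))
      for (col in c("C", "S", "Total")) {
        sel <- ok$phantom == pv & ok$method == m &
          (col == "Total" | ok$region == col)
        v <- ok$mod_mm[sel]
        if (length(v) == 0) next
        s <- mod_describe(v)
        rows[[length(rows) + 1]] <- data.frame(
          phantom = pv, method = m, column = col, n = s$n, min = s$min,
          q25 = s$q25, median = s$median, q75 = s$q75, max = s$max,
          stringsAsFactors = FALSE)
      }
  out <- do.call(rbind, rows)
  attr(out, "off_bone") <- sum(trials$status != "ok")
  class(out) <- c("mod_report", "data.frame")
  out
}

#' @export
print.mod_report <- function(x, digits = 2, ...) {
  cat("Maximum osteotomy deviation (mm) by phantom, method and region\n")
  df <- as.data.frame(x)
  num <- c("min", "q25", "median", "q75", "max")
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  ob <- attr(x, "off_bone")
  if (isTRUE(ob > 0))
    cat(sprintf("(%d off-bone placement(s) excluded from the order statistics)\n", ob))
  invisible(x)
}

#' Inferential comparisons over a trial table
#'
#' The nonparametric analyses of the bench protocol: Kruskal-Wallis and
#' Dunn over guidance methods (all trials pooled), Kruskal-Wallis over
#' cases within each region, and per-method Kruskal-Wallis between
#' phantom variants. Off-bone trials are excluded.
#'
#' @param trials tidy trial data frame.
#' @return List with `kw_methods`, `dunn_methods`, `kw_cases` (per
#'   region) and `kw_phantom` (per method); entries are `NULL` where a
#'   factor has a single level.
#' @export
trial_stats <- function(trials) {
  ok <- trials[trials$status == "ok" & is.finite(trials$mod_mm), , drop = FALSE]
  by_method <- split(ok$mod_mm, ok$method)
  out <- list(kw_methods = NULL, dunn_methods = NULL, kw_cases = list(),
              kw_phantom = list())
  if (length(by_method) >= 2) {
    out$kw_methods <- kruskal_wallis(by_method)
    out$dunn_methods <- dunn_posthoc(by_method)
  }
  for (r in unique(ok$region)) {
    sub <- ok[ok$region == r, ]
    g <- split(sub$mod_mm, sub$case_id)
    if (length(g) >= 2) out$kw_cases[[r]] <- kruskal_wallis(g)
  }
  if (length(unique(ok$phantom)) >= 2)
    for (m in unique(ok$method)) {
      sub <- ok[ok$method == m, ]
      out$kw_phantom[[m]] <- kruskal_wallis(split(sub$mod_mm, sub$phantom))
    }
  out
}

#' @export
print.psi_experiment <- function(x, ...) {
  cat(sprintf("Simulated PSI placement experiment: %d trials (%d users x %d cases x 2 regions x %d methods x %d phantoms)\n",
              nrow(x$trials), x$config$n_users, length(x$cases),
              length(x$config$methods), length(x$config$phantoms)))
  for (v in names(x$registrations))
    cat(sprintf("  %s phantom registration: ICP rms %.2e mm (%d iterations)\n",
                v, x$registrations[[v]]$icp$rms_residual,
                x$registrations[[v]]$icp$iterations))
  print(x$summary)
  if (!is.null(x$stats$kw_methods)) {
    cat("Method effect: ")
    print(x$stats$kw_methods)
  }
  invisible(x)
}

#' @export
summary.psi_experiment <- function(object, ...) {
  print(object)
  if (!is.null(object$stats$dunn_methods)) print(object$stats$dunn_methods)
  for (r in names(object$stats$kw_cases)) {
    cat(sprintf("Case effect in region %s: ", r))
    print(object$stats$kw_cases[[r]])
  }
  for (m in names(object$stats$kw_phantom)) {
    cat(sprintf("Phantom effect for %s: ", m))
    print(object$stats$kw_phantom[[m]])
  }
  invisible(object)
}

#' @export
plot.psi_experiment <- function(x, ...) {
  ok <- x$trials[x$trials$status == "ok", ]
  graphics::boxplot(mod_mm ~ method, data = ok, ylab = "MOD (mm)",
                    xlab = "guidance method", ...)
  invisible(x)
}

#' Read/write the tidy trial table
#'
#' @param trials trial data frame.
#' @param path CSV path.
#' @return `read_trials_csv` returns the validated data frame;
#'   `write_trials_csv` returns `path` invisibly.
#' @export
write_trials_csv <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "region", "method", "phantom", "user", "mod_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trial CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(df$status)) df$status <- "ok"
  df
}
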