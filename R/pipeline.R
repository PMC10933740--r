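#' Run an end-to-end analysis scenario
#'
#' Orchestrates the package's inference chain as named scenarios, each a
#' small DAG of stages sharing one seed; re-running with the same
#' configuration reproduces every number in the report bit-identically.
#' A failing stage is recorded with its error message and its dependent
#' stages are skipped, so a partial report is still returned.
#'
#' Scenarios:
#' \describe{
#'   \item{`reference-lattices`}{regenerates the five (q4, q6) reference
#'     points and their mutual distance table.}
#'   \item{`patchy-sediment`}{settles tetrahedral patchy particles to a
#'     target packing fraction (stage block `patchy`: `n`, `target_phi`,
#'     `steps`, `eps_patch`, ...), then reports bulk contact statistics and
#'     the bond-orientational classification.}
#'   \item{`saxs-roundtrip`}{simulates a noisy SAXS profile from known
#'     parameters (stage block `saxs`: `d_mean`, `d_sd`, `phi`, `noise`) and
#'     fits it back, reporting recovery errors.}
#'   \item{`tomogram-emulation`}{voxelizes an input assembly (stage block
#'     `tomo`: either `input` path or a generated jammed packing), degrades
#'     it, extracts spheres, applies the rescale correction, and compares
#'     contact statistics before/after.}
#' }
#'
#' @param config a [run_config()] (or path to a YAML file).
#' @return An object of class `pipeline_report`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "run_config")) stopf("config must be a run_config")
  scen <- config$scenario
  known <- c("reference-lattices", "patchy-sediment", "saxs-roundtrip",
             "tomogram-emulation")
  if (is.null(scen) || !scen %in% known)
    stopf("unknown scenario '%s'; expected one of: %s",
          scen %||% "<missing>", paste(known, collapse = ", "))
  report <- list(schema = "diamondpack-report/1", scenario = scen,
                 seed = config$seed, config = unclass(config),
                 package_version = as.character(utils::packageVersion("diamondpack")),
                 stages = list())
  t0 <- proc.time()[["elapsed"]]
  run_stage <- function(name, deps = character(), fn) {
    for (d in deps) {
      if (!identical(report$stages[[d]]$status, "ok")) {
        report$stages[[name]] <<- list(status = "skipped",
                                       reason = sprintf("dependency '%s' failed", d))
        return(invisible(NULL))
      }
    }
    ts <- proc.time()[["elapsed"]]
    res <- tryCatch(list(status = "ok", result = fn()),
                    error = function(e) list(status = "error",
                                             message = conditionMessage(e)))
    res$seconds <- round(proc.time()[["elapsed"]] - ts, 3)
    report$stages[[name]] <<- res
    invisible(NULL)
  }
  sb <- function(block) config$stages[[block]] %||% list()

  if (scen == "reference-lattices") {
    run_stage("references", fn = function() {
      refs <- reference_points(gap_tol = config$contact_gap)
      dmat <- outer(seq_len(nrow(refs)), seq_len(nrow(refs)), function(i, j)
        sqrt((refs$q4[i] - refs$q4[j])^2 + (refs$q6[i] - refs$q6[j])^2))
      dimnames(dmat) <- list(refs$label, refs$label)
      list(references = refs, distances = dmat)
    })
  } else if (scen == "patchy-sediment") {
    p <- sb("patchy")
    run_stage("sediment", fn = function() {
      model <- patchy_model(diameter = p$diameter %||% 210,
                            eps_patch = p$eps_patch %||% 8,
                            eps_body = p$eps_body %||% 3)
      st <- sim_settings(dt = p$dt %||% 0.003, steps = p$steps %||% 93000L,
                         seed = config$seed)
      fit <- equilibrate_to_density(model, p$target_phi %||% 0.46,
                                    settings = st, n = p$n %||% 1080)
      list(assembly = fit$assembly, achieved_phi = fit$achieved_phi,
           gravity = fit$gravity, history = fit$history)
    })
    run_stage("contacts", deps = "sediment", fn = function() {
      fit <- report$stages$sediment$result
      bulk <- sediment_bulk(fit$assembly)
      g <- contact_graph(fit$assembly, config$contact_gap)
      deg <- g$degree[bulk$bulk]
      list(phi = bulk$phi,
           n_touch_mean = mean(deg), n_touch_sd = sd(deg),
           histogram = as.list(table(deg)), n_bulk = sum(bulk$bulk),
           gap_tol = config$contact_gap)
    })
    run_stage("boo", deps = "sediment", fn = function() {
      fit <- report$stages$sediment$result
      bulk <- sediment_bulk(fit$assembly)
      b <- averaged_boo(fit$assembly, config$contact_gap,
                        subset = which(bulk$bulk))
      cls <- classify_structure(b$mean["q4"], b$mean["q6"],
                                reference_points(gap_tol = config$contact_gap))
      list(mean = as.list(b$mean), classification = cls$label,
           distances = cls$distances)
    })
  } else if (scen == "saxs-roundtrip") {
    p <- sb("saxs")
    run_stage("simulate", fn = function() {
      truth <- saxs_params(d_mean = p$d_mean %||% 218, d_sd = p$d_sd %||% 26,
                           phi = p$phi %||% 0.49)
      prof <- simulate_saxs_profile(truth, model = p$model %||% "py",
                                    noise = p$noise %||% 0.02,
                                    seed = config$seed)
      list(truth = truth, profile = prof)
    })
    run_stage("fit", deps = "simulate", fn = function() {
      sim <- report$stages$simulate$result
      init <- saxs_params(d_mean = sim$truth$d_mean * 1.15,
                          d_sd = sim$truth$d_mean * 0.05,
                          phi = 0.35, scale = 1.2)
      f <- fit_saxs(sim$profile, model = p$model %||% "py", init = init)
      list(estimate = as.list(f$estimate), se = as.list(f$se),
           chisq_red = f$chisq_red,
           rel_error = list(
             d_mean = abs(f$params$d_mean - sim$truth$d_mean) / sim$truth$d_mean,
             phi = abs(f$params$phi - sim$truth$phi) / sim$truth$phi))
    })
  } else if (scen == "tomogram-emulation") {
    p <- sb("tomo")
    run_stage("input", fn = function() {
      if (!is.null(p$input)) read_assembly(p$input)
      else generate_jammed_packing(p$n %||% 300, polydispersity = 0.05,
                                   seed = config$seed,
                                   diameter = p$diameter %||% 210)
    })
    run_stage("chain", deps = "input", fn = function() {
      truth <- report$stages$input$result
      vol <- voxelize(truth, pitch = config$voxel_pitch)
      shrink <- p$shrink %||% 0.83
      deg <- degrade(vol, degradation_spec(shrink_factor = shrink,
                                           seed = config$seed))
      ext <- extract_spheres(deg, expected_radius =
                               shrink * mean(truth$radii))
      resc <- rescale_assembly(ext, p$rescale %||% 1.2)
      # second correction: replace extracted particles by ideal spheres of
      # the nominal diameter before contact statistics
      resc <- regularize_spheres(resc, 2 * mean(truth$radii))
      # the rescale restores (approximately) the original frame; particles
      # cut at the bounded volume's faces are excluded by an interior margin,
      # as in real tomogram analysis
      m <- 2 * mean(truth$radii)
      interior <- function(pos, box)
        pos[, 1] > m & pos[, 1] < box[1] - m &
        pos[, 2] > m & pos[, 2] < box[2] - m &
        pos[, 3] > m & pos[, 3] < box[3] - m
      tp <- truth$positions
      for (ax in 1:3) tp[, ax] <- tp[, ax] %% truth$box[ax]
      sel_t <- interior(tp, truth$box)
      sel_r <- interior(resc$positions, resc$box)
      g0 <- contact_graph(truth, config$contact_gap)
      g1 <- contact_graph(resc, config$contact_gap)
      list(n_truth = sum(sel_t), n_recovered = sum(sel_r),
           n_touch_truth = mean(g0$degree[sel_t]),
           n_touch_recovered = mean(g1$degree[sel_r]),
           phi_truth = as.numeric(suppressWarnings(
             packing_fraction(truth, "voxel_mc", seed = config$seed))),
           mean_diameter_recovered = 2 * mean(resc$radii[sel_r]))
    })
  }
  report$elapsed_seconds <- round(proc.time()[["elapsed"]] - t0, 3)
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> scenario '%s', seed %d, %.1f s\n",
              x$scenario, x$seed, x$elapsed_seconds))
  for (nm in names(x$stages))
    cat(sprintf("  %-12s %s (%.1f s)\n", nm, x$stages[[nm]]$status,
                x$stages[[nm]]$seconds %||% 0))
  invisible(x)
}

#' Write a pipeline report as JSON
#' @param report a `pipeline_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  clean <- rapply(unclass(report), function(v) {
    if (is.matrix(v)) return(v)
    v
  }, how = "replace")
  jsonlite::write_json(clean, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}
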