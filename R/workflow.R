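# The chained workflow: fuse -> nhp -> plan-apply -> evaluate, driven by a
# config describing the input files. This is what the command-line script
# in inst/cli wraps.

#' Run the digital surgery workflow
#'
#' Executes the requested stages in order, writing every artifact into
#' `out_dir` together with `workflow_log.txt` recording per-stage
#' parameters and residuals. Stages are selected by which inputs the
#' config provides:
#' \describe{
#'   \item{fuse}{`scan` + `model` -> `fusion_transform.json`}
#'   \item{nhp}{`model` + `landmarks` + `photo` -> `nhp.stl`,
#'     `nhp_landmarks.json`}
#'   \item{plan}{`model` + `landmarks` + `plan` -> `simulation.stl`,
#'     `simulation_landmarks.json`, `plan_summary.csv`}
#'   \item{evaluate}{`sim`/`sim_landmarks` (defaulting to the plan stage
#'     outputs) + `postop` + `postop_landmarks` + `cranial_mask` ->
#'     `report.csv`}
#' }
#'
#' @param config named list: file paths `scan`, `model`, `landmarks`,
#'   `photo`, `plan`, `postop`, `postop_landmarks`, `cranial_mask` (JSON
#'   array of vertex indices), optional `focal` (pixels), and parameter
#'   overrides `icp`, `cpd` (lists passed to [icp_params()]/[cpd_params()])
#' @param out_dir output directory, created if needed
#' @param verbose print per-stage messages (default `TRUE`)
#' @return named list of artifact paths, invisibly
#' @export
run_workflow <- function(config, out_dir = ".", verbose = TRUE) {
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "workflow_log.txt")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    if (verbose) message(msg)
    log_lines <<- c(log_lines, msg)
  }
  need <- function(key) {
    p <- config[[key]]
    if (is.null(p)) abort(sprintf("config is missing '%s'", key))
    if (!file.exists(p)) abort(sprintf("input file not found: %s", p))
    p
  }
  artifacts <- list()
  icp <- do.call(icp_params, config$icp %||% list())
  cpd <- do.call(cpd_params, config$cpd %||% list())

  model <- NULL; landmarks <- NULL
  if (!is.null(config$model)) model <- read_stl(need("model"))
  if (!is.null(config$landmarks)) landmarks <- read_landmarks(need("landmarks"))

  if (!is.null(config$scan)) {
    scan <- read_stl(need("scan"))
    say("fuse: scan %d vertices -> model %d vertices",
        nrow(scan$vertices), nrow(model$vertices))
    fres <- fuse_dentition(scan, model, icp, cpd)
    say("fuse: rms %.5f mm after %d iterations", fres$rms, fres$iterations)
    artifacts$fusion_transform <- file.path(out_dir, "fusion_transform.json")
    write_transform(fres$transform, artifacts$fusion_transform)
  }

  if (!is.null(config$photo)) {
    photo <- read_photo_landmarks(need("photo"))
    cam <- camera_model(focal = config$focal %||% 2000)
    nhp <- reproduce_nhp(model, landmarks, photo, cam)
    e <- euler_decompose(nhp$rotation)
    say("nhp: pitch %.3f roll %.3f yaw %.3f deg (residual %.4f px)",
        e[["pitch"]], e[["roll"]], e[["yaw"]], nhp$pose$residual)
    artifacts$nhp_model <- file.path(out_dir, "nhp.stl")
    write_stl(nhp$mesh, artifacts$nhp_model)
    artifacts$nhp_landmarks <- file.path(out_dir, "nhp_landmarks.json")
    write_landmarks(nhp$landmarks, artifacts$nhp_landmarks)
    model <- nhp$mesh; landmarks <- nhp$landmarks
  }

  sim_mesh <- NULL; sim_lm <- NULL
  if (!is.null(config$plan)) {
    plan <- read_plan(need("plan"))
    res <- apply_plan(model, landmarks, plan)
    say("plan: net displacement %s",
        paste(sprintf("%.3f", as.numeric(res$summary[1, ])), collapse = " "))
    artifacts$simulation <- file.path(out_dir, "simulation.stl")
    write_stl(res$mesh, artifacts$simulation)
    artifacts$simulation_landmarks <- file.path(out_dir, "simulation_landmarks.json")
    write_landmarks(res$landmarks, artifacts$simulation_landmarks)
    artifacts$plan_summary <- file.path(out_dir, "plan_summary.csv")
    utils::write.csv(res$summary, artifacts$plan_summary, row.names = FALSE)
    sim_mesh <- res$mesh; sim_lm <- res$landmarks
  }

  if (!is.null(config$postop)) {
    if (!is.null(config$sim)) sim_mesh <- read_stl(need("sim"))
    if (!is.null(config$sim_landmarks)) sim_lm <- read_landmarks(need("sim_landmarks"))
    if (is.null(sim_mesh)) abort("evaluate stage needs a simulation model ('sim' or a plan stage)")
    postop <- read_stl(need("postop"))
    post_lm <- read_landmarks(need("postop_landmarks"))
    mask <- as.integer(unlist(jsonlite::fromJSON(need("cranial_mask"))))
    rep_ <- evaluate_case(sim_mesh, sim_lm, postop, post_lm, mask, icp)
    g <- glance(rep_)
    say("evaluate: mean |dx| %.3f |dy| %.3f |dz| %.3f rms %.3f mm; pitch %.3f roll %.3f yaw %.3f deg",
        g$mean_abs_dx, g$mean_abs_dy, g$mean_abs_dz, g$mean_rms,
        g$pitch, g$roll, g$yaw)
    artifacts$report <- file.path(out_dir, "report.csv")
    write_report_csv(rep_, artifacts$report)
  }

  writeLines(log_lines, log_path)
  artifacts$log <- log_path
  invisible(artifacts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
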