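#' Tracing parameters
#'
#' All tunable parameters of the reconstruction pipeline with their default
#' values; every one can be overridden here or loaded from a YAML file with
#' [read_trace_config()].
#'
#' @param visible_min visibility threshold on the 0-255 scale (default 10).
#' @param keep_fraction fraction of visible voxels kept by binarization
#'   (default 0.7).
#' @param noisy_mode use `noisy_keep_fraction` instead of `keep_fraction`
#'   (for stacks contaminated by heavy noise).
#' @param noisy_keep_fraction binarization fraction in noisy mode
#'   (default 0.2).
#' @param min_comp_2d minimum 2D 8-neighbor component size (default 9 px).
#' @param min_comp_3d minimum 3D 26-neighbor component size (default 30
#'   voxels).
#' @param gap_fraction fragment-bridging limit as a fraction of the largest
#'   image dimension (default 0.05).
#' @param R_um branch-point bonus radius, micrometers (default 1.0).
#' @param eta branch-point bonus scale (default 10).
#' @param prune_ratio minimum branch length relative to the longest branch
#'   (default 0.2).
#' @param bplist_um snap distance to recorded branch points (default 1.0).
#' @param bps2d_um snap distance to candidate 2D branch points
#'   (default 0.75).
#' @param epsilon polyline simplification tolerance in voxel units (default
#'   `sqrt(3)`, the voxel body diagonal).
#' @return A list of class `trace_control`.
#' @export
trace_control <- function(visible_min = 10, keep_fraction = 0.7,
                          noisy_mode = FALSE, noisy_keep_fraction = 0.2,
                          min_comp_2d = 9, min_comp_3d = 30,
                          gap_fraction = 0.05, R_um = 1.0, eta = 10,
                          prune_ratio = 0.2, bplist_um = 1.0,
                          bps2d_um = 0.75, epsilon = sqrt(3)) {
  ctl <- list(visible_min = visible_min, keep_fraction = keep_fraction,
              noisy_mode = isTRUE(noisy_mode),
              noisy_keep_fraction = noisy_keep_fraction,
              min_comp_2d = min_comp_2d, min_comp_3d = min_comp_3d,
              gap_fraction = gap_fraction, R_um = R_um, eta = eta,
              prune_ratio = prune_ratio, bplist_um = bplist_um,
              bps2d_um = bps2d_um, epsilon = epsilon)
  stopifnot(ctl$keep_fraction > 0, ctl$keep_fraction <= 1,
            ctl$noisy_keep_fraction > 0, ctl$noisy_keep_fraction <= 1,
            ctl$eta > 0, ctl$R_um > 0, ctl$epsilon >= 0)
  structure(ctl, class = "trace_control")
}

#' Read or write a tracing configuration as YAML
#'
#' @param path YAML file holding any subset of [trace_control()] fields.
#' @return A `trace_control` list.
#' @export
read_trace_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(trace_control))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  do.call(trace_control, vals)
}

#' @rdname read_trace_config
#' @param control a `trace_control` list.
#' @export
write_trace_config <- function(control, path) {
  yaml::write_yaml(unclass(control), path)
  invisible(path)
}

#' Trace a neuron from an image stack
#'
#' Runs the full reconstruction pipeline: binarization and cleaning,
#' per-slice EDT skeletonization, MST fragment assembly, soma detection,
#' branch-point-weighted Dijkstra tracing, short-branch pruning, branch
#' merging with false-end-point removal, and polyline simplification.
#'
#' @param stack an [image_stack] or a path readable by [read_stack()].
#' @param control a [trace_control()] list.
#' @param keep_intermediates keep the mask, skeleton point set, and raw
#'   branch set in the result (default `FALSE`).
#' @param voxel_size voxel pitch, used when `stack` is a path.
#' @return An object of class `neuron_trace`: `tree` (the simplified
#'   [neuron_tree]), `soma`, `control`, and `report` (per-stage counts and
#'   wall times).
#' @export
trace_neuron <- function(stack, control = trace_control(),
                         keep_intermediates = FALSE,
                         voxel_size = c(x = 0.33, y = 0.33, z = 1.0)) {
  if (is.character(stack)) stack <- read_stack(stack, voxel_size)
  stopifnot(inherits(stack, "image_stack"), inherits(control, "trace_control"))
  report <- list()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
    report$timings[[name]] <<- tic() - t0
    out
  }

  vol <- stage("preprocess", preprocess_stack(stack, control))
  report$voxel_counts <- attr(vol, "counts")
  if (!any(vol$mask))
    stop("stage 'preprocess': empty mask after preprocessing")

  q <- stage("skeleton", skeletonize_slices(vol))
  if (nrow(q$pts) == 0L) stop("stage 'skeleton': empty skeleton point set")
  report$n_skeleton_points <- nrow(q$pts)

  q <- stage("assemble", mst_connect(q, build_component_graph(q, control$gap_fraction)))
  report$n_components_before <- attr(q, "n_components_before")
  report$n_points_assembled <- nrow(q$pts)

  q <- detect_end_candidates(q)
  q <- detect_branch_candidates(q)
  report$n_end_candidates <- sum(q$end)
  report$n_branch_candidates <- sum(q$branch)

  soma <- stage("soma", detect_soma(q, stack, vol))
  report$soma <- list(position_um = unname(soma$position_um),
                      radius_um = soma$radius_um)

  graph <- stage("graph", build_graph(q, control$eta, control$R_um))
  branches <- stage("dijkstra", shortest_path_branches(graph, soma))
  report$n_branches_traced <- length(branches$paths)
  branches <- prune_short_branches(branches, control$prune_ratio)
  report$n_branches_pruned <- report$n_branches_traced - length(branches$paths)
  if (!length(branches$paths))
    stop("stage 'trace': no branches survive pruning")

  tree <- stage("merge", merge_branches(branches, soma,
                                        control$bplist_um, control$bps2d_um))
  report$n_false_endpoints <- attr(tree, "n_false_endpoints")
  report$n_nodes_raw <- nrow(tree)

  tree <- stage("simplify", simplify_tree(tree, control$epsilon, "voxel"))
  report$n_nodes_final <- nrow(tree)

  out <- list(tree = tree, soma = soma, control = control, report = report)
  if (keep_intermediates)
    out$intermediates <- list(mask = vol, skeleton = q, branches = branches)
  structure(out, class = "neuron_trace")
}

#' Trace a batch of stacks
#'
#' Processes each stack independently; one failure never aborts the batch.
#'
#' @param stacks character vector of stack paths, or a list of
#'   [image_stack]s (optionally named).
#' @param control a [trace_control()] list.
#' @param out_dir if given, an SWC file and a JSON run report are written
#'   per stack.
#' @param voxel_size voxel pitch for stacks given as paths.
#' @return data frame with one row per input: `name`, `ok`, `n_nodes`,
#'   `error`; traced results attached as the `results` attribute.
#' @export
run_batch <- function(stacks, control = trace_control(), out_dir = NULL,
                      voxel_size = c(x = 0.33, y = 0.33, z = 1.0)) {
  nm <- names(stacks)
  if (is.null(nm))
    nm <- if (is.character(stacks)) basename(stacks)
          else sprintf("stack_%03d", seq_along(stacks))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  results <- vector("list", length(stacks))
  rows <- vector("list", length(stacks))
  for (i in seq_along(stacks)) {
    res <- tryCatch(
      trace_neuron(if (is.character(stacks)) stacks[[i]] else stacks[[i]],
                   control, voxel_size = voxel_size),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(name = nm[i], ok = FALSE, n_nodes = NA_integer_,
                              error = conditionMessage(res))
    } else {
      results[[i]] <- res
      rows[[i]] <- data.frame(name = nm[i], ok = TRUE,
                              n_nodes = nrow(res$tree), error = NA_character_)
      if (!is.null(out_dir)) {
        write_swc(res$tree, file.path(out_dir, paste0(nm[i], ".swc")))
        jsonlite::write_json(trace_report(res),
                             file.path(out_dir, paste0(nm[i], ".json")),
                             auto_unbox = TRUE, digits = NA)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- results
  out
}

# flatten a trace report for JSON output
trace_report <- function(trace) {
  r <- trace$report
  r$voxel_counts <- as.list(r$voxel_counts)
  r$control <- unclass(trace$control)
  r
}
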