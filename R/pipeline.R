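#' Pipeline configurations
#'
#' An extraction pipeline is an ordered sequence of named steps, each
#' belonging to one of four stages that must appear in pipeline order:
#' `preprocessing` (any number), `segmentation` (at most one),
#' `graph_detection` (an optional `guo_hall` thinning step followed by
#' exactly one `detect` step when the input is an image) and
#' `graph_filtering` (any number).  Configurations serialize losslessly to
#' a versioned YAML document ([save_config()], [load_config()]).
#'
#' Available steps: see [pipeline_steps()].
#'
#' @param steps list of steps created with [pipeline_step()].
#' @return an object of class `"pipeline_config"`.
#' @examples
#' cfg <- pipeline_config(list(
#'   pipeline_step("segmentation", "otsu"),
#'   pipeline_step("graph_detection", "guo_hall"),
#'   pipeline_step("graph_detection", "detect")))
#' cfg
#' @export
pipeline_config <- function(steps) {
  steps <- lapply(steps, function(s) {
    if (!is.list(s) || is.null(s$stage) || is.null(s$name))
      stop("each step needs a stage and a name", call. = FALSE)
    pipeline_step(s$stage, s$name, if (is.null(s$params)) list() else
      s$params)
  })
  validate_steps(steps, input = "any")
  structure(list(version = 1L, steps = steps), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param stage one of `"preprocessing"`, `"segmentation"`,
#'   `"graph_detection"`, `"graph_filtering"`.
#' @param name registered step name.
#' @param params named list of parameters (merged over the step defaults).
#' @export
pipeline_step <- function(stage, name, params = list()) {
  stages <- c("preprocessing", "segmentation", "graph_detection",
              "graph_filtering")
  if (!stage %in% stages)
    stop("unknown pipeline stage: ", stage, call. = FALSE)
  reg <- step_registry()
  if (!name %in% names(reg))
    stop("unknown pipeline step: ", name, call. = FALSE)
  if (reg[[name]]$stage != stage)
    stop(sprintf("step '%s' belongs to stage '%s', not '%s'", name,
                 reg[[name]]$stage, stage), call. = FALSE)
  bad <- setdiff(names(params), names(reg[[name]]$defaults))
  if (length(bad))
    stop(sprintf("unknown parameter(s) for step '%s': %s", name,
                 paste(bad, collapse = ", ")), call. = FALSE)
  params <- lapply(params, function(p)
    if (is.numeric(p)) as.numeric(p) else p)
  if (length(params)) params <- params[order(names(params))]
  list(stage = stage, name = name, params = params)
}

validate_steps <- function(steps, input = "image") {
  stages <- vapply(steps, `[[`, character(1), "stage")
  names_ <- vapply(steps, `[[`, character(1), "name")
  ord <- match(stages, c("preprocessing", "segmentation",
                         "graph_detection", "graph_filtering"))
  if (any(diff(ord) < 0))
    stop("configuration error: pipeline stages out of order (",
         paste(stages, collapse = " -> "), ")", call. = FALSE)
  if (sum(stages == "segmentation") > 1L)
    stop("configuration error: at most one segmentation step", call. = FALSE)
  if (sum(names_ == "detect") > 1L)
    stop("configuration error: at most one detect step", call. = FALSE)
  if (sum(names_ == "guo_hall") > 1L)
    stop("configuration error: at most one thinning step", call. = FALSE)
  if (input == "image" && !any(names_ == "detect") &&
      any(stages == "graph_filtering"))
    stop("configuration error: graph filters require a detect step",
         call. = FALSE)
  invisible(steps)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config v%d, %d steps>\n", x$version,
              length(x$steps)))
  for (s in x$steps) {
    p <- if (length(s$params))
      paste0("(", paste(names(s$params), unlist(s$params), sep = "=",
                        collapse = ", "), ")") else ""
    cat(sprintf("  %-16s %s %s\n", s$stage, s$name, p))
  }
  invisible(x)
}

#' @rdname pipeline_config
#' @export
pipeline_steps <- function() {
  reg <- step_registry()
  tibble::tibble(
    name = names(reg),
    stage = vapply(reg, `[[`, character(1), "stage"),
    params = vapply(reg, function(s)
      paste(names(s$defaults), collapse = ", "), character(1)))
}

#' Save or load a pipeline configuration
#'
#' Configurations are stored as versioned YAML; `save_config()` followed by
#' `load_config()` is the identity.
#'
#' @param config a [pipeline_config()].
#' @param path file path (conventionally `.yml`).
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  doc <- list(netextract_pipeline = config$version,
              steps = lapply(config$steps, function(s)
                list(stage = s$stage, name = s$name, params = s$params)))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  doc <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("parse error in pipeline file '", path, "': ",
         conditionMessage(e), call. = FALSE))
  if (!is.list(doc) || is.null(doc$netextract_pipeline))
    stop("parse error in pipeline file '", path,
         "': missing 'netextract_pipeline' version field", call. = FALSE)
  pipeline_config(doc$steps)
}

#' Predefined pipelines
#'
#' Ready-made configurations shipped with the package: `"otsu"` and
#' `"adaptive"` (threshold, thin, detect), each also in a
#' `"*_largest"` variant that appends the largest-component filter.
#'
#' @param name pipeline name.
#' @return a [pipeline_config()].
#' @export
predefined_pipeline <- function(name = c("otsu", "adaptive",
                                         "otsu_largest",
                                         "adaptive_largest")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("pipeline_", name, ".yml"),
                      package = "netextract", mustWork = TRUE)
  load_config(path)
}

#' Evaluation pipelines for the interchangeable segmentation methods
#'
#' Builds the "threshold/segment, thin, detect" pipeline for one of the
#' seven segmentation methods compared in the benchmark: `otsu`,
#' `adaptive`, `watershed_de` (erosion marker), `watershed_dt`
#' (distance-transform marker), `watershed_ad` (adaptive marker),
#' `grabcut_de`, `grabcut_dt`.  Adaptive-threshold parameters default to a
#' window larger than the widest rendered stroke (see the package
#' vignette).
#'
#' @param method segmentation method name.
#' @param block,offset adaptive-threshold window and margin used by the
#'   adaptive-based methods.
#' @param invert segment dark-on-light structures.
#' @param merge_radius node-merge radius passed to the detect step; the
#'   benchmark protocol merges the split single-pixel nodes that any
#'   skeleton detector produces at junctions (default 12 px at the 1024-px
#'   render scale).
#' @return a [pipeline_config()].
#' @export
method_pipeline <- function(method = c("otsu", "adaptive", "watershed_de",
                                       "watershed_dt", "watershed_ad",
                                       "grabcut_de", "grabcut_dt"),
                            block = 51, offset = 10, invert = FALSE,
                            merge_radius = 12) {
  method <- match.arg(method)
  seg_params <- switch(method,
    otsu = list(invert = invert),
    adaptive = list(block = block, offset = offset, invert = invert),
    watershed_ad = list(block = block, offset = offset, invert = invert),
    list(invert = invert))
  pipeline_config(list(
    pipeline_step("segmentation", method, seg_params),
    pipeline_step("graph_detection", "guo_hall"),
    pipeline_step("graph_detection", "detect",
                  list(merge_radius = merge_radius)),
    pipeline_step("graph_filtering", "smooth")))
}

# ---------------------------------------------------------------------------
# Step registry: name -> stage, defaults, fn(state, params) -> state
# ---------------------------------------------------------------------------

step_registry <- function() {
  if (!is.null(.netex$registry)) return(.netex$registry)
  reg <- list(
    gaussian_blur = list(
      stage = "preprocessing", defaults = list(kernel = 5, sigma = NULL),
      fn = function(st, p) {
        st$image <- gaussian_blur(st$image, p$kernel, p$sigma); st
      }),
    median_blur = list(
      stage = "preprocessing", defaults = list(kernel = 5),
      fn = function(st, p) {
        st$image <- median_blur(st$image, p$kernel); st
      }),
    bilateral = list(
      stage = "preprocessing",
      defaults = list(diameter = 9, sigma_color = 75, sigma_space = 75),
      fn = function(st, p) {
        st$image <- bilateral_filter(st$image, p$diameter, p$sigma_color,
                                     p$sigma_space); st
      }),
    nlmeans = list(
      stage = "preprocessing", defaults = list(strength = 10),
      fn = function(st, p) {
        st$image <- denoise_nlmeans(st$image, p$strength); st
      }),
    otsu = list(
      stage = "segmentation", defaults = list(invert = FALSE),
      fn = function(st, p) {
        st$binary <- seg_otsu(st$image, invert = p$invert); st
      }),
    adaptive = list(
      stage = "segmentation",
      defaults = list(block = 11, offset = 2, invert = FALSE),
      fn = function(st, p) {
        st$binary <- seg_adaptive(st$image, p$block, p$offset, p$invert); st
      }),
    watershed_de = list(
      stage = "segmentation",
      defaults = list(iterations = 2, invert = FALSE),
      fn = function(st, p) {
        guess <- seg_otsu(st$image, invert = p$invert)
        st$binary <- seg_watershed(st$image,
                                   marker_erosion(guess, p$iterations))
        st
      }),
    watershed_dt = list(
      stage = "segmentation",
      defaults = list(fraction = 0.7, iterations = 2, invert = FALSE),
      fn = function(st, p) {
        guess <- seg_otsu(st$image, invert = p$invert)
        st$binary <- seg_watershed(
          st$image,
          marker_distance_transform(guess, p$fraction, p$iterations))
        st
      }),
    watershed_ad = list(
      stage = "segmentation",
      defaults = list(block = 51, offset = 10, iterations = 2,
                      invert = FALSE),
      fn = function(st, p) {
        st$binary <- seg_watershed(
          st$image,
          marker_adaptive(st$image, p$block, p$offset, p$iterations,
                          p$invert))
        st
      }),
    grabcut_de = list(
      stage = "segmentation",
      defaults = list(iterations = 2, grabcut_iterations = 5,
                      invert = FALSE),
      fn = function(st, p) {
        guess <- seg_otsu(st$image, invert = p$invert)
        st$binary <- seg_grabcut(st$image, marker_erosion(guess,
                                                          p$iterations),
                                 iterations = p$grabcut_iterations)
        st
      }),
    grabcut_dt = list(
      stage = "segmentation",
      defaults = list(fraction = 0.7, iterations = 2,
                      grabcut_iterations = 5, invert = FALSE),
      fn = function(st, p) {
        guess <- seg_otsu(st$image, invert = p$invert)
        st$binary <- seg_grabcut(
          st$image,
          marker_distance_transform(guess, p$fraction, p$iterations),
          iterations = p$grabcut_iterations)
        st
      }),
    external_binary = list(
      stage = "segmentation", defaults = list(threshold = 127),
      fn = function(st, p) {
        st$binary <- binary_image(img_gray(st$image) > p$threshold); st
      }),
    guo_hall = list(
      stage = "graph_detection", defaults = list(),
      fn = function(st, p) {
        if (is.null(st$binary))
          stop("configuration error: thinning requires a segmentation",
               call. = FALSE)
        st$skeleton <- guo_hall_thin(st$binary); st
      }),
    detect = list(
      stage = "graph_detection",
      defaults = list(merge_radius = 0, min_loop = 3),
      fn = function(st, p) {
        if (is.null(st$binary))
          stop("configuration error: detect requires a segmentation",
               call. = FALSE)
        st$graph <- detect_graph(st$binary, skeleton = st$skeleton,
                                 merge_radius = p$merge_radius,
                                 min_loop = p$min_loop)
        st
      }),
    largest_component = list(
      stage = "graph_filtering", defaults = list(),
      fn = function(st, p) { st$graph <- keep_largest_component(st$graph); st }),
    smooth = list(
      stage = "graph_filtering", defaults = list(),
      fn = function(st, p) { st$graph <- smooth_degree_two(st$graph); st }),
    cycles = list(
      stage = "graph_filtering", defaults = list(),
      fn = function(st, p) { st$graph <- keep_cycles(st$graph); st })
  )
  .netex$registry <- reg
  reg
}

.netex <- new.env(parent = emptyenv())

#' Run an extraction pipeline
#'
#' Executes the configured steps in order on an input image and captures
#' every intermediate result.  The pipeline is deterministic: the same
#' configuration on the same image always yields the same result.
#'
#' @param image a [raster_image()]; a [binary_image()] may be supplied to
#'   enter the pipeline at graph detection; a [spatial_graph()] to apply
#'   graph filters only.
#' @param config a [pipeline_config()].
#' @return a `pipeline_result`: list with `intermediates` (named list, one
#'   entry per executed step in order) and `final_graph`.
#' @examples
#' m <- matrix(20, 48, 48); m[23:25, 5:44] <- 220
#' res <- run_pipeline(raster_image(m), predefined_pipeline("otsu"))
#' res$final_graph
#' @export
run_pipeline <- function(image, config) {
  stopifnot(inherits(config, "pipeline_config"))
  st <- list(image = NULL, binary = NULL, skeleton = NULL, graph = NULL)
  input <- "image"
  if (inherits(image, "spatial_graph")) {
    st$graph <- image; input <- "graph"
  } else if (is_binary_image(image)) {
    st$binary <- image
    st$image <- raster_image(unclass(image) * 255)
  } else {
    if (!is_raster_image(image)) image <- raster_image(image)
    st$image <- image
  }
  validate_steps(config$steps, input = input)
  names_ <- vapply(config$steps, `[[`, character(1), "name")
  if (input == "image" && !is_binary_image(image) &&
      !any(names_ == "detect"))
    stop("configuration error: a detect step is required for image input",
         call. = FALSE)
  reg <- step_registry()
  inter <- list()
  for (i in seq_along(config$steps)) {
    s <- config$steps[[i]]
    entry <- reg[[s$name]]
    p <- modifyList(entry$defaults, s$params)
    st <- entry$fn(st, p)
    out <- switch(s$stage,
                  preprocessing = st$image,
                  segmentation = st$binary,
                  graph_detection = if (s$name == "guo_hall") st$skeleton
                    else st$graph,
                  graph_filtering = st$graph)
    inter[[sprintf("%02d_%s", i, s$name)]] <- out
  }
  structure(list(intermediates = inter, final_graph = st$graph),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result: %d steps>\n", length(x$intermediates)))
  for (nm in names(x$intermediates)) cat("  ", nm, "\n")
  if (!is.null(x$final_graph)) print(x$final_graph)
  invisible(x)
}
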