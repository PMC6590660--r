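## End-to-end quantification pipeline: volumes in, quantitative maps out.

# resolve a protocol entry: bundled name or path to a YAML file
.resolve_protocol <- function(x) {
  if (inherits(x, "mp2rage_protocol")) return(x)
  if (is.null(x)) stop("config is missing the 'protocol' key", call. = FALSE)
  if (file.exists(x)) return(read_protocol(x))
  example_protocol(x)
}

# load one data source: either a phantom spec or file paths
.load_source <- function(src, p) {
  if (!is.null(src$phantom)) {
    args <- src$phantom
    if (!is.null(args$grid_shape)) args$grid_shape <- as.integer(unlist(args$grid_shape))
    if (!is.null(args$b1_range)) args$b1_range <- as.numeric(unlist(args$b1_range))
    cfg <- do.call(phantom_config, args)
    generate_phantom(cfg, p)
  } else if (!is.null(src$inputs)) {
    inp <- src$inputs
    for (k in c("inv1_mag", "inv1_phase", "inv2_mag", "inv2_phase"))
      if (is.null(inp[[k]])) stop("config 'inputs' misses '", k, "'", call. = FALSE)
    tes <- if (!is.null(inp$tes)) as.numeric(unlist(inp$tes)) else p$te2
    out <- list(inv1_mag = read_volume(inp$inv1_mag),
                inv1_phase = read_volume(inp$inv1_phase),
                inv2_mag = read_volume(inp$inv2_mag),
                inv2_phase = read_volume(inp$inv2_phase),
                b1 = if (!is.null(inp$b1)) read_volume(inp$b1) else NULL,
                tes = tes, truth = NULL)
    if (!is.null(inp$labels)) out$truth <- list(labels = read_volume(inp$labels))
    out
  } else {
    stop("config must provide either 'phantom' or 'inputs'", call. = FALSE)
  }
}

# UNI volume from magnitude+phase of the two inversions (first echo of block 2)
.uni_from_volumes <- function(vols) {
  z1 <- vols$inv1_mag * exp(1i * vols$inv1_phase)
  nd <- length(dim(vols$inv2_mag))
  idx <- if (nd == 4L) slice.index(vols$inv2_mag, 4L) == 1L else TRUE
  m2 <- if (nd == 4L) array(vols$inv2_mag[idx], dim(vols$inv1_mag)) else vols$inv2_mag
  p2 <- if (nd == 4L) array(vols$inv2_phase[idx], dim(vols$inv1_mag)) else vols$inv2_phase
  z2 <- m2 * exp(1i * p2)
  u <- Re(z1 * Conj(z2)) / (Mod(z1)^2 + Mod(z2)^2)
  u[!is.finite(u)] <- 0
  array(pmin(pmax(u, -0.5), 0.5), dim(vols$inv1_mag))
}

# quantify one source against a lookup table; returns maps + roi table
.quantify <- function(vols, lut, tissue_names, log_add) {
  uni <- .uni_from_volumes(vols)
  n_warn <- 0L
  t1res <- withCallingHandlers(
    t1_from_uni(uni, vols$b1, lut),
    warning = function(w) { n_warn <<- n_warn + 1L; invokeRestart("muffleWarning") })
  log_add("t1_map", n_warn)

  ne <- dim(vols$inv2_mag)[length(dim(vols$inv2_mag))]
  fit <- t2star_fit(vols$inv2_mag, vols$tes[seq_len(ne)])
  log_add("t2star_map", 0L)

  roi <- NULL
  if (!is.null(vols$truth$labels)) {
    roi_t1 <- roi_medians(t1res$t1_map, vols$truth$labels, tissue_names)
    roi_t2 <- roi_medians(fit$t2star, vols$truth$labels, tissue_names)
    roi <- merge(roi_t1, roi_t2, by = c("label", "name"),
                 suffixes = c("_t1", "_t2star"))
    roi <- roi[order(roi$label), ]
    log_add("roi_medians", 0L)
  }
  list(uni = uni, t1_map = t1res$t1_map, validity_mask = t1res$validity_mask,
       t2star_map = fit$t2star, s0_map = fit$s0, t2star_valid = fit$valid,
       roi = roi)
}

#' Run the full quantification pipeline from a configuration
#'
#' Executes the standard processing chain: obtain volumes (from a synthetic
#' phantom specification or from NIfTI files), combine the two inversion
#' images into a UNI volume, build the lookup table for the named protocol,
#' decode T1 with transmit-field correction, fit T2* from the second-block
#' echoes, summarize over regions when a label volume is available, and
#' optionally compare against a second source with Bland-Altman statistics.
#' All maps, tables and a structured log are written to \code{outdir} when
#' one is configured.
#'
#' The configuration is a YAML file or an equivalent named list with keys:
#' \code{protocol} (bundled name or YAML path); one of \code{phantom}
#' (arguments for [phantom_config()]) or \code{inputs} (paths
#' \code{inv1_mag}, \code{inv1_phase}, \code{inv2_mag}, \code{inv2_phase},
#' optional \code{b1}, \code{labels}, and \code{tes} in ms); optional
#' \code{lookup} (grid overrides \code{t1_min}, \code{t1_max},
#' \code{t1_step}, \code{b1_min}, \code{b1_max}, \code{b1_step}); optional
#' \code{compare} (a second \code{phantom}/\code{inputs} source); optional
#' \code{outdir}.
#'
#' If no transmit-field map is available the pipeline proceeds at nominal
#' transmit with a prominent warning (uncorrected mode).
#'
#' @param config Path to a YAML configuration or a named list.
#' @return A list with the UNI volume, \code{t1_map}, \code{validity_mask},
#'   \code{t2star_map}, \code{s0_map}, the ROI table (or \code{NULL}), the
#'   \code{agreement} statistics when a comparison source was configured, and
#'   the structured \code{log}.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("'config' must be a YAML path or a named list")
  p <- .resolve_protocol(cfg$protocol)

  log <- list(); t0 <- proc.time()[["elapsed"]]
  log_add <- function(stage, warnings = 0L) {
    log[[length(log) + 1L]] <<- list(
      stage = stage, elapsed_s = round(proc.time()[["elapsed"]] - t0, 3),
      warnings = warnings)
  }
  log_add("config")

  vols <- .load_source(cfg, p)
  log_add("load")

  lk <- cfg$lookup
  gv <- function(key, default) if (is.null(lk[[key]])) default else as.numeric(lk[[key]])
  lut <- build_lookup(
    p,
    t1_grid = seq(gv("t1_min", 0.1), gv("t1_max", 6.0), by = gv("t1_step", 0.001)),
    b1_grid = seq(gv("b1_min", 0.6), gv("b1_max", 1.4), by = gv("b1_step", 0.01)))
  log_add("lookup")

  tissue_names <- if (inherits(vols, "volume_set"))
    vols$config$tissue_table[, c("label", "name")] else default_tissues()[, c("label", "name")]
  q <- .quantify(vols, lut, tissue_names, log_add)

  agreement <- NULL
  if (!is.null(cfg$compare)) {
    vols2 <- .load_source(cfg$compare, p)
    q2 <- .quantify(vols2, lut, tissue_names, function(...) NULL)
    if (!is.null(q$roi) && !is.null(q2$roi)) {
      # region-level agreement, as conventional for quantitative-map comparisons
      m <- merge(q$roi, q2$roi, by = c("label", "name"))
      m <- m[m$n_t1.x > 0 & m$n_t1.y > 0, ]
      agreement <- bland_altman(m$median_t1.x, m$median_t1.y)
    } else {
      ok <- q$validity_mask & q2$validity_mask
      i <- which(ok)
      if (length(i) > 20000L) i <- i[seq(1L, length(i), length.out = 20000L)]
      agreement <- bland_altman(q$t1_map[i], q2$t1_map[i])
    }
    log_add("compare")
  }

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    vs <- if (inherits(vols, "volume_set")) vols$voxel_size else 1
    wv <- function(v, name) write_volume(ifelse(is.finite(v), v, 0),
                                         file.path(cfg$outdir, name), vs)
    wv(q$uni, "uni.nii.gz")
    wv(q$t1_map, "t1.nii.gz")
    wv(q$t2star_map, "t2star.nii.gz")
    wv(q$s0_map, "s0.nii.gz")
    wv(q$validity_mask + 0, "validity.nii.gz")
    if (!is.null(q$roi))
      utils::write.csv(q$roi, file.path(cfg$outdir, "roi.csv"), row.names = FALSE)
    log_add("write")
    meta <- list(package_version = as.character(utils::packageVersion("mp2rageme")),
                 protocol = p$name,
                 seed = if (!is.null(cfg$phantom$seed)) cfg$phantom$seed else NA,
                 stages = log)
    jsonlite::write_json(meta, file.path(cfg$outdir, "log.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(uni = q$uni, t1_map = q$t1_map, validity_mask = q$validity_mask,
       t2star_map = q$t2star_map, s0_map = q$s0_map, roi = q$roi,
       agreement = agreement, protocol = p, log = log)
}
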