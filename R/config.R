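#' Default run configuration
#'
#' Collects every tunable of the reconstruction pipeline in one flat-ish list
#' that can be stored as YAML.  Values not supplied fall back to the defaults
#' below.
#'
#' @param ... named overrides, e.g. `pn_config(cgmm = list(max_iter = 50))`.
#'   Sub-lists are merged element-wise.
#' @return a named list of configuration sections.
#' @export
pn_config <- function(...) {
  base <- list(
    foreground = list(
      threshold = 0.5          # field threshold; points strictly above kept
    ),
    cgmm = list(
      epsilon0 = 128,          # minimum 8-bit intensity at a cluster center
      neurite_diameter = 6,    # voxels; epsilon1 = (3 * diameter)^3
      seed_exclusion_radius = 5,
      density_cutoff_radius = 3,
      stop_tol = 0.01,         # relative parameter-change criterion
      max_iter = 100,
      split_gamma = "sd",      # daughter offset = sqrt(lead eigenvalue)/2
      literal_det_rescale = FALSE
    ),
    mvce = list(
      feas_tol = 1e-7,
      gap_tol = 1e-7,
      max_newton_iter = 200,
      split_depth = 4
    ),
    linking = list(
      auxiliary_cost = 100,    # dummy value; also the link rejection threshold
      repair_cost = 20,        # threshold for orphan-repair assignment rounds
      resample_spacing = 1
    ),
    mift = list(
      smooth_window = 5,       # nodes averaged per direction estimate
      split_cos_threshold = 0.5,  # cut links with vertex angle sharper than 60 deg
      merge_radius = 8,        # block level; fusion levels use 8, 12, 16
      max_revision_rounds = 6,
      absorb_tol = 2,          # redundancy tolerance for debris absorption
      absorb_max_nodes = 40    # debris fragments larger than this are kept
    ),
    fusion = list(
      margin = 5,              # boundary-node distance to the shared face
      fit_window = 10,         # nodes in the local line fit
      auxiliary_cost = 20,
      merge_radii = c(8, 12, 16)
    ),
    metrics = list(
      match_tol = 4            # voxels; point-matching tolerance
    ),
    swc = list(
      radius = 3               # emitted neurite radius (voxels)
    )
  )
  merge_config(base, list(...))
}

merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config()` returns a full configuration (file values override
#'   defaults); `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pn_config, vals %||% list())
}

#' @rdname read_config
#' @param config a configuration list from [pn_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
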