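#' Read and write wing morphologies as structured config
#'
#' Morphologies are exchanged as YAML: named membrane patches with
#' vertex lists, thickness and density, and setae as records with a
#' base point, either a direction + length or a tip, and a linear
#' density. All lengths in um, densities in internal units.
#'
#' @param wing a [wing_morphology()].
#' @param path file path (`.yaml`).
#' @return `read_morphology()` returns a [wing_morphology()];
#'   `write_morphology()` returns `path` invisibly.
#' @export
write_morphology <- function(wing, path) {
  stopifnot(inherits(wing, "wing_morphology"))
  patch_to_list <- function(p) {
    if (is.null(p)) return(NULL)
    list(vertices = apply(p$boundary, 1, as.list),
         thickness = p$thickness, density = p$density)
  }
  obj <- list(
    petiole = patch_to_list(wing$petiole),
    blade = patch_to_list(wing$blade),
    setae = purrr::map(wing$setae, function(s) {
      list(base = as.list(s$base), direction = as.list(s$direction),
           length = s$length, linear_density = s$linear_density)
    }),
    base_frame = list(origin = as.list(wing$base_frame$origin),
                      axes = apply(wing$base_frame$axes, 2, as.list))
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_morphology
#' @param seta_base_tol passed to [wing_morphology()].
#' @export
read_morphology <- function(path, seta_base_tol = Inf) {
  if (!file.exists(path)) stop("morphology file not found: ", path, call. = FALSE)
  obj <- yaml::read_yaml(path)
  list_to_patch <- function(l) {
    if (is.null(l)) return(NULL)
    bnd <- do.call(rbind, lapply(l$vertices, unlist))
    membrane_patch(bnd, thickness = l$thickness, density = l$density)
  }
  setae <- purrr::map(obj$setae, function(s) {
    seta_rod(base = unlist(s$base), direction = unlist(s$direction),
             length = s$length, linear_density = s$linear_density)
  })
  frame <- NULL
  if (!is.null(obj$base_frame)) {
    frame <- list(origin = unlist(obj$base_frame$origin),
                  axes = do.call(cbind, lapply(obj$base_frame$axes, unlist)))
  }
  wing_morphology(petiole = list_to_patch(obj$petiole),
                  blade = list_to_patch(obj$blade),
                  setae = setae, base_frame = frame,
                  seta_base_tol = seta_base_tol)
}
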