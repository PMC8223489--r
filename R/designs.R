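# Registry of hexagonal peptide-pattern designs.
#
# Each design places 6 peptide docking sites on the vertices of a regular
# hexagon whose edge length is the nominal inter-site spacing of that
# pattern (the mean of the six edge lengths reported for the folded
# structures). Per-design super-resolution oversampling factors are the
# rendering settings used when calling sites inside a structure ROI.

.design_edges_nm <- c(
  W6 = 5.7, W9 = 9.43, W16 = 15.8, W19 = 18.8, W26 = 25.5,
  L6 = 6.3, L11 = 11.1, W37 = 37
)

# Oversampling by nominal-size class: 37 -> 60x, 28 -> 60x, 19 -> 100x,
# 16 -> 120x, 9 -> 120x, 5 -> 150x. L6 falls in the 5 nm class, L11 in
# the 9 nm class.
.design_oversampling <- c(
  W37 = 60L, W26 = 60L, W19 = 100L, W16 = 120L, W9 = 120L,
  W6 = 150L, L6 = 150L, L11 = 120L
)

#' Names of all registered pattern designs
#'
#' @return Character vector of registered design names.
#' @export
list_designs <- function() names(.design_edges_nm)

#' Vertices of a regular hexagon
#'
#' Returns the six vertices of a regular hexagon centered at the origin
#' with circumradius equal to `edge_nm` (for a regular hexagon the
#' circumradius and the edge length coincide), rotated by `rotation`.
#'
#' @param edge_nm Edge length in nm; must be positive.
#' @param rotation Rotation angle in radians (counter-clockwise).
#' @return A 6 x 2 numeric matrix with columns `x`, `y` (nm).
#' @examples
#' hexagon_coords(5.7)
#' @export
hexagon_coords <- function(edge_nm, rotation = 0) {
  if (!is.numeric(edge_nm) || length(edge_nm) != 1L || !is.finite(edge_nm) ||
      edge_nm <= 0) {
    stop("`edge_nm` must be a single positive number", call. = FALSE)
  }
  ang <- rotation + (0:5) * pi / 3
  cbind(x = edge_nm * cos(ang), y = edge_nm * sin(ang))
}

#' Retrieve a registered pattern design
#'
#' @param name Design name, one of `list_designs()`.
#' @return A `design_spec` object: a list with elements `name`,
#'   `nominal_edge_nm`, `n_sites` (always 6), `site_coords_nm`
#'   (6 x 2 matrix, nm, pattern-local frame) and `oversampling`
#'   (super-resolution rendering factor used for site calling).
#' @examples
#' get_design("W6")$nominal_edge_nm  # 5.7
#' @export
get_design <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !(name %in% names(.design_edges_nm))) {
    stop(
      "unknown design ", deparse(substitute(name)), ": valid names are ",
      paste(names(.design_edges_nm), collapse = ", "),
      call. = FALSE
    )
  }
  edge <- unname(.design_edges_nm[[name]])
  structure(
    list(
      name = name,
      nominal_edge_nm = edge,
      n_sites = 6L,
      site_coords_nm = hexagon_coords(edge),
      oversampling = unname(.design_oversampling[[name]])
    ),
    class = "design_spec"
  )
}

#' Super-resolution oversampling factor for a design
#'
#' @inheritParams get_design
#' @return Positive integer oversampling factor.
#' @export
analysis_oversampling <- function(name) get_design(name)$oversampling

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf(
    "<design_spec> %s: regular hexagon, edge %.3g nm, %d sites, %dx oversampling\n",
    x$name, x$nominal_edge_nm, x$n_sites, x$oversampling
  ))
  invisible(x)
}

#' Export the design registry to a file
#'
#' Writes the registry as a list of records with fields `name`,
#' `nominal_edge_nm` and `oversampling` (site coordinates are derived,
#' not stored).
#'
#' @param path Output file path.
#' @param format `"yaml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_design_registry <- function(path, format = c("yaml", "json")) {
  format <- match.arg(format)
  recs <- lapply(list_designs(), function(nm) {
    d <- get_design(nm)
    list(name = d$name, nominal_edge_nm = d$nominal_edge_nm,
         oversampling = d$oversampling)
  })
  if (format == "yaml") {
    yaml::write_yaml(recs, path)
  } else {
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a design registry file
#'
#' @param path File written by [write_design_registry()].
#' @param format `"yaml"` or `"json"`.
#' @return A list of `design_spec` objects (regular-hexagon geometry is
#'   regenerated from each record's edge length).
#' @export
read_design_registry <- function(path, format = c("yaml", "json")) {
  format <- match.arg(format)
  recs <- if (format == "yaml") yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(r) {
    for (f in c("name", "nominal_edge_nm", "oversampling")) {
      if (is.null(r[[f]])) stop("registry record missing field: ", f, call. = FALSE)
    }
    structure(
      list(
        name = r$name,
        nominal_edge_nm = r$nominal_edge_nm,
        n_sites = 6L,
        site_coords_nm = hexagon_coords(r$nominal_edge_nm),
        oversampling = as.integer(r$oversampling)
      ),
      class = "design_spec"
    )
  })
}
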