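#' Built-in element property table
#'
#' Masses in atomic mass units; van der Waals radii in nm (Bondi-type values).
#' GRO files carry neither, so every atom entering the pipeline is assigned
#' mass and radius from this table, keyed on the element inferred from its
#' atom name (see [infer_element()]), with optional per-name overrides.
#'
#' @return A data.frame with columns `element`, `mass` (amu) and
#'   `vdw_radius` (nm).
#' @export
element_properties <- function() {
  data.frame(
    element = c("H", "C", "N", "O", "P", "S", "K", "NA", "CL", "MG", "CA", "ZN", "F"),
    mass = c(1.008, 12.011, 14.007, 15.999, 30.974, 32.06, 39.098,
             22.990, 35.45, 24.305, 40.078, 65.38, 18.998),
    vdw_radius = c(0.120, 0.170, 0.155, 0.152, 0.180, 0.180, 0.275,
                   0.227, 0.175, 0.173, 0.231, 0.139, 0.147),
    stringsAsFactors = FALSE
  )
}

#' Infer the chemical element from a GRO atom name
#'
#' Standard GRO practice: the element is encoded in the leading alphabetic
#' characters of the atom name ("OW" is a water oxygen, "HW1" a water
#' hydrogen, "C12" a carbon). The full alphabetic prefix is matched first so
#' ion names like "K", "NA" or "CL" resolve to the ion, then the first
#' character is used as fallback.
#'
#' @param name Character vector of atom names.
#' @return Character vector of element symbols; `NA` where inference fails.
#' @export
infer_element <- function(name) {
  known <- element_properties()$element
  prefix <- toupper(sub("[^A-Za-z].*$", "", name))
  first <- substr(prefix, 1L, 1L)
  out <- ifelse(prefix %in% known, prefix,
                ifelse(first %in% known, first, NA_character_))
  out[prefix == ""] <- NA_character_
  out
}

# Attach element, mass and vdw_radius columns to a bare atom table.
# `overrides`: optional data.frame(name, mass, vdw_radius) applied by atom name.
assign_atom_properties <- function(atoms, overrides = NULL) {
  props <- element_properties()
  atoms$element <- infer_element(atoms$name)
  if (anyNA(atoms$element)) {
    bad <- unique(atoms$name[is.na(atoms$element)])
    stop("cannot infer element for atom name(s): ", paste(bad, collapse = ", "),
         "; supply overrides", call. = FALSE)
  }
  m <- match(atoms$element, props$element)
  atoms$mass <- props$mass[m]
  atoms$vdw_radius <- props$vdw_radius[m]
  if (!is.null(overrides)) {
    stopifnot(is.data.frame(overrides), "name" %in% names(overrides))
    hit <- match(atoms$name, overrides$name)
    sel <- !is.na(hit)
    if ("mass" %in% names(overrides)) {
      atoms$mass[sel] <- overrides$mass[hit[sel]]
    }
    if ("vdw_radius" %in% names(overrides)) {
      atoms$vdw_radius[sel] <- overrides$vdw_radius[hit[sel]]
    }
  }
  if (any(atoms$mass <= 0) || any(atoms$vdw_radius <= 0)) {
    stop("masses and vdW radii must be positive", call. = FALSE)
  }
  atoms
}
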