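#' Individual-tree basal area
#'
#' Cross-sectional stem area at breast height of a single tree, from its
#' diameter at breast height.
#'
#' @param dbh Diameter at breast height in cm (vectorised, all values > 0).
#' @return Basal area in m^2: `pi * dbh^2 / 40000`.
#' @examples
#' tree_basal_area(20)          # 0.0314 m^2
#' tree_basal_area(200 / sqrt(pi))  # exactly 1 m^2
#' @export
tree_basal_area <- function(dbh) {
  if (!is.numeric(dbh) || any(!is.finite(dbh)) || any(dbh <= 0)) {
    stop("'dbh' must be finite and > 0", call. = FALSE)
  }
  pi * dbh^2 / 40000
}

#' Default species classification table
#'
#' Lookup table mapping species codes to the broadleaf/coniferous class used
#' throughout the matching and downscaling steps. Codes follow the usual
#' abbreviation of the latin binomial (e.g. `Fa.sy.` for *Fagus sylvatica*).
#' Two pseudo-species (`Brd.cc.`, `Con.cc.`) represent counted-but-not-measured
#' small-tree categories of simplified inventories, where trees below a dbh
#' threshold are only tallied by class; they carry `counted_class = TRUE` so
#' validation can exclude them.
#'
#' @return A data.frame with columns `species`, `broadleaf` (logical) and
#'   `counted_class` (logical).
#' @export
default_species_classes <- function() {
  data.frame(
    species = c("Fa.sy.", "Fr.ex.", "Ac.ps.", "Qu.pe.", "Qu.un.", "Qu.ru.",
                "Be.pe.", "Al.gl.", "Ca.be.", "Ti.co.", "Pr.se.", "OtherBrd.",
                "Pi.ab.", "Ab.al.", "Pi.sy.", "La.de.", "OtherCon.",
                "Brd.cc.", "Con.cc."),
    broadleaf = c(rep(TRUE, 12), rep(FALSE, 5), TRUE, FALSE),
    counted_class = c(rep(FALSE, 17), TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

# Map species codes to a logical broadleaf flag, failing fast on any species
# absent from the classification table.
species_broadleaf <- function(species, classes = default_species_classes()) {
  idx <- match(species, classes$species)
  if (anyNA(idx)) {
    missing <- unique(species[is.na(idx)])
    stop("species without broadleaf/coniferous classification: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  classes$broadleaf[idx]
}

#' Stand-level summary of a tree list
#'
#' Computes the three stand variables used both as model responses and as the
#' plot-matching space: total basal area (BA, m^2/ha), quadratic mean diameter
#' (Dg, cm) and the proportion of stand basal area contributed by broadleaf
#' species (BA_b, in \[0, 1\]).
#'
#' Dg is the diameter of the tree of mean basal area:
#' `Dg^2` equals the weight-weighted mean of squared dbh exactly.
#'
#' @param trees Data frame with columns `species`, `dbh` (cm) and `weight`
#'   (stems/ha; may be fractional). Zero rows are allowed.
#' @param classes Species classification table, see
#'   [default_species_classes()].
#' @return A list with elements `BA`, `Dg`, `BA_b`. An empty tree list gives
#'   `(0, 0, 0)`; `BA_b` of an empty (or conifer-only) stand is 0.
#' @export
stand_summary <- function(trees, classes = default_species_classes()) {
  if (is.null(trees) || nrow(trees) == 0) {
    return(list(BA = 0, Dg = 0, BA_b = 0))
  }
  stopifnot(all(c("species", "dbh", "weight") %in% names(trees)))
  if (any(trees$dbh <= 0)) stop("all dbh must be > 0", call. = FALSE)
  if (any(trees$weight <= 0)) stop("all weights must be > 0", call. = FALSE)
  broad <- species_broadleaf(trees$species, classes)
  ba <- tree_basal_area(trees$dbh) * trees$weight
  BA <- sum(ba)
  Dg <- sqrt(sum(trees$weight * trees$dbh^2) / sum(trees$weight))
  BA_b <- if (BA > 0) sum(ba[broad]) / BA else 0
  list(BA = BA, Dg = Dg, BA_b = BA_b)
}

#' Read a field-plot tree table
#'
#' Reads a delimited text file with one row per tree, columns `plot_id`,
#' `species`, `dbh_cm`, `weight_ha`, optional `height_m`, `stratum`, optional
#' `forest_type`.
#'
#' @param path Path to a CSV file.
#' @return Data frame of trees.
#' @export
read_plot_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "species", "dbh_cm", "weight_ha")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("plot table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Split a tree table into a list of field plots
#'
#' @param df Tree table as returned by [read_plot_table()].
#' @return Named list of plots; each plot is a list with `plot_id`, `trees`
#'   (data frame with `species`, `dbh`, `weight`, optional `height`),
#'   `stratum` and `forest_type`.
#' @export
split_plots <- function(df) {
  ids <- unique(df$plot_id)
  out <- lapply(ids, function(id) {
    rows <- df[df$plot_id == id, , drop = FALSE]
    trees <- data.frame(
      species = rows$species,
      dbh = rows$dbh_cm,
      weight = rows$weight_ha,
      stringsAsFactors = FALSE
    )
    if ("height_m" %in% names(rows)) trees$height <- rows$height_m
    list(
      plot_id = id,
      trees = trees,
      stratum = if ("stratum" %in% names(rows)) rows$stratum[1] else NA_character_,
      forest_type = if ("forest_type" %in% names(rows)) rows$forest_type[1] else NA_character_
    )
  })
  names(out) <- as.character(ids)
  out
}

#' Per-hectare weight of a fully enumerated tree
#'
#' For nested plot designs every tree measured on a plot component of area
#' `a` m^2 represents `10000 / a` stems per hectare.
#'
#' @param area_m2 Plot-component area in m^2.
#' @return Stems per hectare.
#' @export
plot_component_weight <- function(area_m2) {
  stopifnot(is.numeric(area_m2), all(area_m2 > 0))
  10000 / area_m2
}
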