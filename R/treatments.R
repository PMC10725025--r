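#' Treatment definitions
#'
#' A treatment assigns a sucrose concentration (% w/w) to each flower
#' orientation plus the per-flower reward volume. The three standard
#' treatments of the slippery-flower trade-off design are:
#' control (35/35), low_difference (vertical 50 / horizontal 35), and
#' high_difference (vertical 50 / horizontal 20).
#'
#' @param name Treatment name.
#' @param conc_vertical,conc_horizontal Concentrations, % w/w, in (0, 70].
#' @param reward_volume Reward per flower, uL.
#' @return A `treatment` object (named list).
#' @examples
#' treatment("high_difference", 50, 20)
#' default_treatments()
#' @export
treatment <- function(name, conc_vertical, conc_horizontal,
                      reward_volume = 15) {
  for (c_ in c(conc_vertical, conc_horizontal))
    if (!is.numeric(c_) || c_ <= 0 || c_ > 70)
      stop_beeforage("config", "concentrations must lie in (0, 70] % w/w")
  if (reward_volume <= 0)
    stop_beeforage("config", "reward_volume must be > 0")
  if (identical(name, "control") && conc_vertical != conc_horizontal)
    stop_beeforage("config",
                   "control treatment requires equal concentrations")
  structure(list(name = name,
                 conc_vertical = conc_vertical,
                 conc_horizontal = conc_horizontal,
                 reward_volume = reward_volume),
            class = "treatment")
}

#' @rdname treatment
#' @export
default_treatments <- function() {
  list(control = treatment("control", 35, 35),
       low_difference = treatment("low_difference", 50, 35),
       high_difference = treatment("high_difference", 50, 20))
}

# orientation -> concentration lookup for a treatment (or a raw named map)
concentration_map <- function(treatment) {
  if (inherits(treatment, "treatment"))
    return(c(vertical = treatment$conc_vertical,
             horizontal = treatment$conc_horizontal))
  if (is.numeric(treatment) &&
      all(c("vertical", "horizontal") %in% names(treatment)))
    return(treatment[c("vertical", "horizontal")])
  stop_beeforage("config",
                 "need a treatment object or a named vector with ",
                 "'vertical' and 'horizontal' concentrations")
}

#' Bee metadata table
#'
#' Construct/validate the bee metadata table: one row per bee with its
#' colony, treatment and unladen mass. Masses are carried in grams
#' internally; the CSV interface stores `unladen_mass_mg`.
#'
#' @param bee_id,colony_id Character identifiers.
#' @param treatment Treatment name, one of control, low_difference,
#'   high_difference.
#' @param unladen_mass Unladen mass in grams, strictly positive.
#' @return data.frame of class `bee_metadata`.
#' @export
bee_metadata <- function(bee_id, colony_id, treatment, unladen_mass) {
  df <- data.frame(bee_id = as.character(bee_id),
                   colony_id = as.character(colony_id),
                   treatment = as.character(treatment),
                   unladen_mass = as.numeric(unladen_mass),
                   stringsAsFactors = FALSE)
  validate_bee_metadata(df)
}

validate_bee_metadata <- function(df) {
  need <- c("bee_id", "colony_id", "treatment", "unladen_mass")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_beeforage("schema", "bee metadata missing column(s): ",
                   paste(miss, collapse = ", "))
  if (anyDuplicated(df$bee_id))
    stop_beeforage("validation", "duplicated bee_id in metadata")
  if (any(!is.finite(df$unladen_mass)) || any(df$unladen_mass <= 0))
    stop_beeforage("validation", "unladen_mass must be strictly positive")
  bad <- setdiff(unique(df$treatment),
                 c("control", "low_difference", "high_difference"))
  if (length(bad))
    stop_beeforage("validation", "unknown treatment(s): ",
                   paste(bad, collapse = ", "))
  class(df) <- c("bee_metadata", "data.frame")
  df
}

#' Read / write bee metadata CSV
#'
#' Columns: bee_id, colony_id, treatment, unladen_mass_mg. Mass is converted
#' to grams on read.
#'
#' @param path CSV path.
#' @param metadata A `bee_metadata` data.frame.
#' @return `read_bee_metadata`: validated `bee_metadata` data.frame.
#' @export
read_bee_metadata <- function(path) {
  if (!file.exists(path))
    stop_beeforage("schema", "bee metadata file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"unladen_mass_mg" %in% names(df))
    stop_beeforage("schema", "bee metadata missing column(s): unladen_mass_mg")
  df$unladen_mass <- df$unladen_mass_mg / 1000
  df$unladen_mass_mg <- NULL
  validate_bee_metadata(df)
}

#' @rdname read_bee_metadata
#' @export
write_bee_metadata <- function(metadata, path) {
  metadata <- validate_bee_metadata(metadata)
  out <- data.frame(bee_id = metadata$bee_id,
                    colony_id = metadata$colony_id,
                    treatment = metadata$treatment,
                    unladen_mass_mg = metadata$unladen_mass * 1000)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
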