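# Single source of truth for the 32 facial soft-tissue landmarks, their
# region ("organ") assignment, left-right pairing, and per-region output
# sizes. Ordering is fixed: it determines the layout of every network output
# vector.

.organLevels <- c("eyes", "nose", "lips", "chin", "right_face", "left_face")

# One row per landmark. Within each region paired points appear right before
# left; definitions are standard anthropometric descriptions.
.registryRows <- local({
  r <- function(name, abbr, organ, lat, def)
    data.frame(name = name, abbreviation = abbr, organ = organ,
               laterality = lat, definition_text = def,
               stringsAsFactors = FALSE)
  pair <- function(base, abbr, organ, def) {
    rbind(r(paste0(base, "_right"), abbr, organ, "right", def),
          r(paste0(base, "_left"), abbr, organ, "left", def))
  }
  rbind(
    # eyes (8)
    pair("Endocanthion", "En", "eyes",
         "Soft-tissue point at the inner commissure of the eye fissure"),
    pair("Exocanthion", "Ex", "eyes",
         "Soft-tissue point at the outer commissure of the eye fissure"),
    pair("Palpebrale_superius", "Ps", "eyes",
         "Highest point on the free margin of the upper eyelid"),
    pair("Palpebrale_inferius", "Pi", "eyes",
         "Lowest point on the free margin of the lower eyelid"),
    # nose (7)
    r("Glabella", "G", "nose", "midline",
      "Most prominent midline point of the forehead between the eyebrows"),
    r("Nasion", "Na", "nose", "midline",
      "Midline point of the nasal root at the level of the nasofrontal junction"),
    r("Pronasale", "Pn", "nose", "midline",
      "Most anteriorly protruding point of the nasal tip"),
    r("Subnasale", "Sn", "nose", "midline",
      "Midline point where the nasal septum meets the upper lip (philtrum)"),
    r("Subspinale", "A", "nose", "midline",
      "Deepest midline point of the concavity below the anterior nasal spine"),
    pair("Alare", "Al", "nose",
         "Most lateral point on the wing of the nose"),
    # lips (7)
    r("Labiale_superius", "Ls", "lips", "midline",
      "Midpoint of the vermilion border of the upper lip"),
    r("Stomion", "Sto", "lips", "midline",
      "Midline point of the labial fissure with the lips gently closed"),
    r("Labiale_inferius", "Li", "lips", "midline",
      "Midpoint of the vermilion border of the lower lip"),
    pair("Christa_philtra", "Cph", "lips",
         "Point on the raised philtral ridge just above the vermilion border"),
    pair("Cheilion", "Ch", "lips",
         "Outer corner of the mouth where the vermilion edges meet"),
    # chin (4)
    r("Sublabiale", "B", "chin", "midline",
      "Deepest midline point of the labiomental fold below the lower lip"),
    r("Pogonion", "Pg", "chin", "midline",
      "Most anterior midline point of the soft-tissue chin"),
    r("Gnathion", "Gn", "chin", "midline",
      "Midline point midway between pogonion and menton on the chin contour"),
    r("Menton", "Me", "chin", "midline",
      "Most inferior midline point of the soft-tissue chin"),
    # face: right lateral (3) then left lateral (3)
    r("Tragus_right", "Tra", "right_face", "right",
      "Most convex point of the tragus of the external ear"),
    r("Zygion_right", "Zy", "right_face", "right",
      "Most lateral point over the zygomatic arch"),
    r("Gonion_right", "Go", "right_face", "right",
      "Point on the rounded angle of the mandible bisecting the ramus and corpus margins"),
    r("Tragus_left", "Tra", "left_face", "left",
      "Most convex point of the tragus of the external ear"),
    r("Zygion_left", "Zy", "left_face", "left",
      "Most lateral point over the zygomatic arch"),
    r("Gonion_left", "Go", "left_face", "left",
      "Point on the rounded angle of the mandible bisecting the ramus and corpus margins")
  )
})

#' The 32-landmark registry
#'
#' Returns the canonical registry of the 32 facial soft-tissue landmarks:
#' name, abbreviation, region assignment (one of eyes, nose, lips, chin,
#' right_face, left_face), laterality (left/right/midline) and a textual
#' definition. Row order is the canonical output ordering used by every
#' network: regions in the fixed order above, paired points right before
#' left.
#'
#' @return data.frame with 32 rows and columns \code{name},
#'   \code{abbreviation}, \code{organ}, \code{laterality},
#'   \code{definition_text}.
#' @examples
#' nrow(landmarkRegistry())  # 32
#' @export
landmarkRegistry <- function() .registryRows

#' Names of the six facial regions
#'
#' @return character vector of length 6, in canonical order.
#' @export
organNames <- function() .organLevels

#' Per-region landmark specification
#'
#' @param organ one of \code{organNames()}.
#' @return list with \code{organ}, ordered \code{landmark_names}, and
#'   \code{n_landmarks} (the per-region network output count N; the network
#'   regresses 3N coordinates).
#' @examples
#' organSpec("chin")$n_landmarks  # 4
#' @export
organSpec <- function(organ) {
  if (length(organ) != 1L || !organ %in% .organLevels)
    stop("unknown organ '", paste(organ, collapse = ","),
         "'; valid organs: ", paste(.organLevels, collapse = ", "))
  reg <- landmarkRegistry()
  nm <- reg$name[reg$organ == organ]
  list(organ = organ, landmark_names = nm, n_landmarks = length(nm))
}

#' Left-right symmetric landmark pairs
#'
#' @return data.frame with 10 rows and columns \code{abbreviation},
#'   \code{left}, \code{right}: each pair shares an abbreviation and differs
#'   only in laterality. Midline landmarks never appear.
#' @export
symmetricPairs <- function() {
  reg <- landmarkRegistry()
  lf <- reg[reg$laterality == "left", ]
  rt <- reg[reg$laterality == "right", ]
  data.frame(abbreviation = rt$abbreviation,
             left = lf$name[match(rt$abbreviation, lf$abbreviation)],
             right = rt$name, stringsAsFactors = FALSE)
}

#' Export the registry as JSON
#'
#' Writes the full registry (name, abbreviation, organ, laterality,
#' definition_text) as a JSON array for downstream tools.
#'
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeRegistryJSON <- function(path) {
  jsonlite::write_json(landmarkRegistry(), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
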