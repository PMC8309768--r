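#' Landmark configuration of one fish
#'
#' Seven named anatomical landmarks in millimetres, in the fixed digitizing
#' order: (1) mouth, (2) posterior dorsal skull, (3) anterior dorsal fin,
#' (4) caudal fin, (5) anterior anal fin, (6) ventral surface, (7) ventral
#' anterior skull.
#'
#' @param fish_id Identifier.
#' @param landmarks_mm 7 x 2 numeric matrix of (x, y) in mm.
#' @param site Site label.
#' @param sex `"male"`, `"female"`, or `"unknown"`.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(fish_id, landmarks_mm, site = "unknown",
                         sex = "unknown") {
  landmarks_mm <- as.matrix(landmarks_mm)
  if (!is.numeric(landmarks_mm) || nrow(landmarks_mm) != 7L ||
      ncol(landmarks_mm) != 2L) {
    stop("landmark_set: landmarks_mm must be a 7 x 2 numeric matrix",
         call. = FALSE)
  }
  if (!all(is.finite(landmarks_mm))) {
    stop("landmark_set: non-finite landmark coordinates", call. = FALSE)
  }
  if (!sex %in% c("male", "female", "unknown")) {
    stop("landmark_set: sex must be male, female, or unknown", call. = FALSE)
  }
  dimnames(landmarks_mm) <- list(landmark_names(), c("x", "y"))
  structure(list(fish_id = fish_id, site = site, sex = sex,
                 landmarks_mm = landmarks_mm),
            class = "landmark_set")
}

landmark_names <- function() {
  c("mouth", "post_dorsal_skull", "ant_dorsal_fin", "caudal_fin",
    "ant_anal_fin", "ventral_surface", "vent_ant_skull")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> fish %s (%s, %s), centroid size %.3g mm\n",
              as.character(x$fish_id), as.character(x$site), x$sex,
              centroid_size(x$landmarks_mm)))
  invisible(x)
}

#' Read a TPS landmark file
#'
#' Parses the TPS dialect written by landmark-digitizing tools: blocks headed
#' by `LM=7`, followed by seven whitespace-separated `x y` coordinate lines
#' and optional `IMAGE=`, `ID=`, and `SCALE=` records. When `SCALE=` is
#' present the coordinates are multiplied by it to yield millimetres;
#' otherwise `default_scale` is used, and its absence is an error (raw pixel
#' coordinates have no physical unit).
#'
#' Site and sex labels are attached from an optional sidecar metadata table
#' with columns `id`, `site`, `sex`, keyed by the block's `IMAGE=` (without
#' extension) or `ID=` value; the TPS format itself has no such fields.
#'
#' @param path Path to the TPS file.
#' @param metadata Optional data frame (`id`, `site`, `sex`) or path to a
#'   comma/tab-delimited file with those columns.
#' @param default_scale mm-per-unit applied to blocks lacking `SCALE=`.
#' @return A list of [landmark_set()] objects, in file order.
#' @export
read_tps <- function(path, metadata = NULL, default_scale = NULL) {
  if (!file.exists(path)) stop("read_tps: file not found: ", path, call. = FALSE)
  if (is.character(metadata)) {
    metadata <- read.table(metadata, header = TRUE, sep = "",
                           stringsAsFactors = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (!length(starts)) stop("read_tps: no LM= blocks found", call. = FALSE)
  bounds <- c(starts, length(lines) + 1L)

  out <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    block <- lines[bounds[b]:(bounds[b + 1L] - 1L)]
    nlm <- as.integer(sub("^LM\\s*=\\s*", "", block[1L], ignore.case = TRUE))
    if (is.na(nlm) || nlm != 7L) {
      stop(sprintf("read_tps: block %d declares LM=%s; exactly 7 landmarks required",
                   b, sub("^LM\\s*=\\s*", "", block[1L])), call. = FALSE)
    }
    coord_lines <- block[-1L][!grepl("=", block[-1L], fixed = TRUE)]
    if (length(coord_lines) != 7L) {
      stop(sprintf("read_tps: block %d has %d coordinate lines, expected 7",
                   b, length(coord_lines)), call. = FALSE)
    }
    xy <- t(vapply(strsplit(coord_lines, "\\s+"), function(p) {
      v <- suppressWarnings(as.numeric(p))
      if (length(v) != 2L || anyNA(v)) {
        stop(sprintf("read_tps: malformed coordinate line in block %d", b),
             call. = FALSE)
      }
      v
    }, numeric(2)))
    kv <- function(key) {
      hit <- grep(paste0("^", key, "\\s*="), block, ignore.case = TRUE)
      if (length(hit)) sub(paste0("^", key, "\\s*=\\s*"), "", block[hit[1L]],
                           ignore.case = TRUE) else NA_character_
    }
    scale <- suppressWarnings(as.numeric(kv("SCALE")))
    if (is.na(scale)) {
      if (is.null(default_scale)) {
        stop(sprintf(
          "read_tps: block %d has no SCALE= and no default_scale was given; coordinates have no unit",
          b), call. = FALSE)
      }
      scale <- default_scale
    }
    id <- kv("ID")
    image <- kv("IMAGE")
    fish_id <- if (!is.na(image)) sub("\\.[^.]*$", "", image)
               else if (!is.na(id)) id else paste0("specimen_", b)
    site <- "unknown"; sex <- "unknown"
    if (!is.null(metadata)) {
      hit <- match(fish_id, as.character(metadata$id))
      if (!is.na(hit)) {
        site <- as.character(metadata$site[hit])
        sex <- as.character(metadata$sex[hit])
      }
    }
    out[[b]] <- landmark_set(fish_id, xy * scale, site = site, sex = sex)
  }
  out
}

#' Write landmark sets to a TPS file
#'
#' Inverse of [read_tps()]: one `LM=7` block per specimen with an `ID=` record
#' and `SCALE=1` (coordinates are already in mm).
#'
#' @param sets List of [landmark_set()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tps <- function(sets, path) {
  lines <- unlist(lapply(seq_along(sets), function(i) {
    lm <- sets[[i]]$landmarks_mm
    c("LM=7",
      sprintf("%.10g %.10g", lm[, 1L], lm[, 2L]),
      paste0("ID=", as.character(sets[[i]]$fish_id)),
      "SCALE=1.0")
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Sidecar metadata for a list of landmark sets
#' @noRd
landmark_metadata <- function(sets) {
  data.frame(
    fish_id = vapply(sets, function(s) as.character(s$fish_id), character(1)),
    site = vapply(sets, function(s) as.character(s$site), character(1)),
    sex = vapply(sets, function(s) s$sex, character(1)),
    stringsAsFactors = FALSE
  )
}
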