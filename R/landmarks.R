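#' Named anatomical landmark set
#'
#' A landmark set is a labelled collection of 3D points in mm. Labels are
#' unique; correspondence between two sets is always established by label,
#' never by row order. Bilateral structures use paired `-L` / `-R` suffixes.
#'
#' @param points n x 3 numeric matrix of coordinates (mm).
#' @param labels character vector of unique anatomical labels.
#' @return matrix of class `ua_landmarks` with labels as row names.
#' @export
ua_landmarks <- function(points, labels = rownames(points)) {
  points <- matrix(as.numeric(points), ncol = 3,
                   dimnames = list(labels, c("x", "y", "z")))
  if (is.null(labels) || anyDuplicated(labels))
    stop("landmark labels must be present and unique")
  if (!all(is.finite(points)))
    stop("landmark coordinates must be finite")
  lr <- grep("-(L|R)$", labels, value = TRUE)
  base <- unique(sub("-(L|R)$", "", lr))
  for (b in base) {
    if (!all(paste0(b, c("-L", "-R")) %in% labels))
      stop("bilateral landmark '", b, "' is missing its L or R partner")
  }
  structure(points, class = c("ua_landmarks", "matrix"))
}

#' Read / write landmark sets as JSON
#'
#' Format: a JSON object mapping each label to its `[x, y, z]` coordinates
#' in mm, e.g. `{"frontozygomatic-L": [-41.2, 30.0, 96.1], ...}`.
#'
#' @param path JSON file path.
#' @return [read_landmarks_json()] returns a `ua_landmarks` object.
#' @export
read_landmarks_json <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- do.call(rbind, lst)
  ua_landmarks(pts, names(lst))
}

#' @rdname read_landmarks_json
#' @param landmarks a `ua_landmarks` object to serialise.
#' @export
write_landmarks_json <- function(landmarks, path) {
  lst <- lapply(seq_len(nrow(landmarks)),
                function(i) unname(landmarks[i, ]))
  names(lst) <- rownames(landmarks)
  jsonlite::write_json(lst, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
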