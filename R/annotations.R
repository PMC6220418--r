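SPIKELET_LABELS <- c("background", "closed", "open")

#' Parse a VOC-style bounding-box annotation file
#'
#' Reads the LabelImg XML dialect
#' (`<object><name>...</name><bndbox><xmin>...</xmin>...</bndbox></object>`).
#' VOC boxes are 1-based and inclusive with `x` running along columns and
#' `y` along rows; they are converted at this boundary to the package's
#' internal convention of 0-based, half-open `[row_min, row_max) x
#' [col_min, col_max)` boxes.
#'
#' @param path Path to the XML file (or an XML string).
#' @param image_dim Optional `c(rows, cols)`; boxes are validated against
#'   it when supplied.
#' @return A data frame with columns `label`, `row_min`, `col_min`,
#'   `row_max`, `col_max`; zero rows if the file annotates no objects.
#' @export
parse_annotations <- function(path, image_dim = NULL) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed annotation XML (", if (file.exists(path)) path else "inline",
         "): ", conditionMessage(e), call. = FALSE))
  objs <- xml2::xml_find_all(doc, ".//object")
  if (!length(objs)) return(empty_annotations())
  get_num <- function(node, tag) {
    v <- xml2::xml_double(xml2::xml_find_first(node, paste0(".//", tag)))
    if (is.na(v)) stop("object missing <", tag, "> in annotation XML")
    v
  }
  ann <- do.call(rbind, lapply(objs, function(o) {
    label <- xml2::xml_text(xml2::xml_find_first(o, ".//name"))
    data.frame(label = label,
               row_min = get_num(o, "ymin") - 1, col_min = get_num(o, "xmin") - 1,
               row_max = get_num(o, "ymax"),     col_max = get_num(o, "xmax"),
               stringsAsFactors = FALSE)
  }))
  validate_annotations(ann, image_dim)
  ann
}

empty_annotations <- function() {
  data.frame(label = character(0), row_min = numeric(0), col_min = numeric(0),
             row_max = numeric(0), col_max = numeric(0))
}

#' Validate an annotation data frame
#'
#' Checks labels against the three spikelet classes and bounding boxes for
#' positive extent and, when `image_dim` is given, containment in the
#' image.
#'
#' @param annotations Annotation data frame (see [parse_annotations()]).
#' @param image_dim Optional `c(rows, cols)` bounds.
#' @return The validated data frame, invisibly.
#' @export
validate_annotations <- function(annotations, image_dim = NULL) {
  stopifnot(is.data.frame(annotations))
  bad <- setdiff(unique(annotations$label), SPIKELET_LABELS)
  if (length(bad))
    stop("unknown annotation label(s): ", paste(bad, collapse = ", "),
         " (expected background/closed/open)")
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    if (a$row_min >= a$row_max || a$col_min >= a$col_max)
      stop(sprintf("object %d ('%s'): degenerate bounding box [%g,%g) x [%g,%g)",
                   i, a$label, a$row_min, a$row_max, a$col_min, a$col_max))
    if (a$row_min < 0 || a$col_min < 0)
      stop(sprintf("object %d ('%s'): bounding box has negative origin", i,
                   a$label))
    if (!is.null(image_dim) && (a$row_max > image_dim[1] || a$col_max > image_dim[2]))
      stop(sprintf("object %d ('%s'): bounding box exceeds image bounds %d x %d",
                   i, a$label, image_dim[1], image_dim[2]))
  }
  invisible(annotations)
}

#' Write annotations as a VOC-style XML file
#'
#' Inverse of [parse_annotations()]: internal 0-based half-open boxes are
#' written back out as 1-based inclusive VOC boxes, so write -> parse is a
#' round trip.
#'
#' @inheritParams validate_annotations
#' @param path Output path.
#' @param image_dim `c(rows, cols)` of the annotated image.
#' @param filename Image filename recorded in the header.
#' @export
write_annotations <- function(annotations, path, image_dim,
                              filename = "frame.png") {
  validate_annotations(annotations, image_dim)
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", filename)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(image_dim[2]))
  xml2::xml_add_child(size, "height", as.character(image_dim[1]))
  xml2::xml_add_child(size, "depth", "3")
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "name", a$label)
    bb <- xml2::xml_add_child(obj, "bndbox")
    xml2::xml_add_child(bb, "xmin", as.character(a$col_min + 1))
    xml2::xml_add_child(bb, "ymin", as.character(a$row_min + 1))
    xml2::xml_add_child(bb, "xmax", as.character(a$col_max))
    xml2::xml_add_child(bb, "ymax", as.character(a$row_max))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
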