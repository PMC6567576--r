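## PASCAL VOC XML dialect. VOC boxes are 1-based and inclusive; the internal
## representation is 0-based and half-open, so the conversion is exactly
## invertible: internal (xmin, xmax) <-> VOC (xmin + 1, xmax).

#' Convert an internal box to VOC XML fields
#'
#' @param box a [BoundingBox-class] (0-based half-open).
#' @return Named list with 1-based inclusive `xmin`, `ymin`, `xmax`, `ymax`
#'   and `name`.
#' @examples
#' boxToVoc(boundingBox(0, 0, 10, 5))  # xmin=1, ymin=1, xmax=10, ymax=5
#' @export
boxToVoc <- function(box) {
  list(name = box@label,
       xmin = as.integer(round(box@xmin)) + 1L,
       ymin = as.integer(round(box@ymin)) + 1L,
       xmax = as.integer(round(box@xmax)),
       ymax = as.integer(round(box@ymax)))
}

#' Convert VOC XML fields to an internal box
#'
#' @param xmin,ymin,xmax,ymax 1-based inclusive VOC coordinates.
#' @param label category name.
#' @return A [BoundingBox-class].
#' @export
vocToBox <- function(xmin, ymin, xmax, ymax, label = "object") {
  if (xmax < xmin || ymax < ymin)
    stop("malformed VOC box: xmax/ymax smaller than xmin/ymin", call. = FALSE)
  boundingBox(xmin - 1, ymin - 1, xmax, ymax, label = label)
}

writeVocXml <- function(boxes, imageFile, shape, channels, path) {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", basename(imageFile))
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(shape[2]))
  xml2::xml_add_child(size, "height", as.character(shape[1]))
  xml2::xml_add_child(size, "depth", as.character(channels))
  for (b in boxes) {
    v <- boxToVoc(b)
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "name", v$name)
    bb <- xml2::xml_add_child(obj, "bndbox")
    for (fld in c("xmin", "ymin", "xmax", "ymax"))
      xml2::xml_add_child(bb, fld, as.character(v[[fld]]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

readVocXml <- function(path) {
  doc <- xml2::read_xml(path)
  objs <- xml2::xml_find_all(doc, ".//object")
  boxes <- lapply(objs, function(o) {
    num <- function(fld)
      as.numeric(xml2::xml_text(xml2::xml_find_first(o, paste0(".//bndbox/", fld))))
    vals <- vapply(c("xmin", "ymin", "xmax", "ymax"), num, 0)
    if (anyNA(vals))
      stop("malformed VOC annotation in ", path, ": missing bndbox field",
           call. = FALSE)
    vocToBox(vals["xmin"], vals["ymin"], vals["xmax"], vals["ymax"],
             label = xml2::xml_text(xml2::xml_find_first(o, ".//name")))
  })
  boxes
}
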