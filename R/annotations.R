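## Annotation readers/writers. Internal convention everywhere: 0-based,
## continuous pixel coordinates (x_min, y_min, x_max, y_max). COCO stores
## (x, y, w, h) with the same origin; Pascal VOC stores 1-based inclusive
## pixel indices, so xmin_voc = x_min + 1 and xmax_voc = x_max. Dialect
## conversion happens only at this IO boundary.

num_chr <- function(x) sprintf("%.17g", x)

#' Write COCO-dialect annotations
#'
#' @param boxes data frame with `image_id` and internal box columns.
#' @param image_ids character vector of all image ids (images without boxes
#'   are still listed).
#' @param path output JSON file.
#' @param width,height image dimensions recorded in the `images` table.
#' @export
write_coco_annotations <- function(boxes, image_ids, path, width, height) {
  images <- lapply(seq_along(image_ids), function(i)
    list(id = i, file_name = paste0(image_ids[i], ".png"),
         width = width, height = height))
  id_of <- stats::setNames(seq_along(image_ids), image_ids)
  anns <- list()
  if (nrow(boxes)) anns <- lapply(seq_len(nrow(boxes)), function(k) {
    b <- boxes[k, ]
    list(id = k, image_id = unname(id_of[[as.character(b$image_id)]]),
         category_id = 1,
         bbox = c(b$x_min, b$y_min, b$x_max - b$x_min, b$y_max - b$y_min),
         area = (b$x_max - b$x_min) * (b$y_max - b$y_min), iscrowd = 0)
  })
  obj <- list(images = images, annotations = anns,
              categories = list(list(id = 1, name = "polyp")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read COCO-dialect annotations
#'
#' Converts COCO `bbox = [x, y, w, h]` to the internal
#' `(x_min, y_min, x_max, y_max)` convention. Image ids are the file-name
#' stems.
#'
#' @param path COCO JSON file.
#' @return data frame `(image_id, x_min, y_min, x_max, y_max)`.
#' @export
read_coco_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed COCO JSON in ", path, ": ",
                                           conditionMessage(e)))
  stems <- vapply(obj$images, function(im)
    sub("\\.[A-Za-z]+$", "", im$file_name), character(1))
  names(stems) <- vapply(obj$images, function(im) as.character(im$id), character(1))
  rows <- lapply(seq_along(obj$annotations), function(k) {
    a <- obj$annotations[[k]]
    bb <- unlist(a$bbox)
    if (length(bb) != 4L || any(!is.finite(bb)))
      stop("malformed bbox in annotation #", k, " of ", path)
    data.frame(image_id = stems[[as.character(a$image_id)]],
               x_min = bb[1], y_min = bb[2],
               x_max = bb[1] + bb[3], y_max = bb[2] + bb[4])
  })
  if (length(rows)) do.call(rbind, rows)
  else data.frame(image_id = character(0), x_min = numeric(0),
                  y_min = numeric(0), x_max = numeric(0), y_max = numeric(0))
}

#' Write one Pascal VOC XML annotation file
#'
#' Coordinates are written as 1-based inclusive pixel indices
#' (`xmin = x_min + 1`, `xmax = x_max`), at full floating precision so that
#' a VOC round trip reproduces the internal boxes exactly.
#'
#' @param boxes data frame of internal boxes for one image.
#' @param path output XML file.
#' @param filename image file name stored in the annotation.
#' @param width,height image dimensions.
#' @export
write_voc_annotation <- function(boxes, path, filename, width, height) {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", filename)
  sz <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(sz, "width", as.character(width))
  xml2::xml_add_child(sz, "height", as.character(height))
  xml2::xml_add_child(sz, "depth", "3")
  if (nrow(boxes)) for (k in seq_len(nrow(boxes))) {
    ob <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(ob, "name", "polyp")
    xml2::xml_add_child(ob, "difficult", "0")
    bb <- xml2::xml_add_child(ob, "bndbox")
    xml2::xml_add_child(bb, "xmin", num_chr(boxes$x_min[k] + 1))
    xml2::xml_add_child(bb, "ymin", num_chr(boxes$y_min[k] + 1))
    xml2::xml_add_child(bb, "xmax", num_chr(boxes$x_max[k]))
    xml2::xml_add_child(bb, "ymax", num_chr(boxes$y_max[k]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read one Pascal VOC XML annotation file
#'
#' Applies the 1-based inclusive reading: `x_min = xmin - 1`,
#' `x_max = xmax`.
#'
#' @param path XML file.
#' @return data frame `(image_id, x_min, y_min, x_max, y_max)`.
#' @export
read_voc_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed VOC XML in ", path, ": ",
                                           conditionMessage(e)))
  fn <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  stem <- sub("\\.[A-Za-z]+$", "", basename(if (is.na(fn)) path else fn))
  objs <- xml2::xml_find_all(doc, "./object")
  rows <- lapply(seq_along(objs), function(k) {
    bb <- xml2::xml_find_first(objs[[k]], "./bndbox")
    get <- function(nm) {
      v <- as.numeric(xml2::xml_text(xml2::xml_find_first(bb, paste0("./", nm))))
      if (!is.finite(v)) stop("malformed <", nm, "> in object #", k, " of ", path)
      v
    }
    data.frame(image_id = stem, x_min = get("xmin") - 1, y_min = get("ymin") - 1,
               x_max = get("xmax"), y_max = get("ymax"))
  })
  if (length(rows)) do.call(rbind, rows)
  else data.frame(image_id = character(0), x_min = numeric(0),
                  y_min = numeric(0), x_max = numeric(0), y_max = numeric(0))
}

#' Load annotations of either dialect
#'
#' `dialect = "auto"` infers COCO from a `.json` extension and VOC from a
#' `.xml` file or a directory of XML files.
#'
#' @param path JSON file, XML file, or directory of VOC XML files.
#' @param dialect `"auto"`, `"coco"` or `"voc"`.
#' @return data frame `(image_id, x_min, y_min, x_max, y_max)`.
#' @export
load_annotations <- function(path, dialect = c("auto", "coco", "voc")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (dir.exists(path) || grepl("\\.xml$", path, TRUE)) "voc"
    else if (grepl("\\.json$", path, TRUE)) "coco"
    else stop("cannot infer annotation dialect from: ", path)
  }
  if (dialect == "coco") return(read_coco_annotations(path))
  files <- if (dir.exists(path)) list.files(path, "\\.xml$", full.names = TRUE)
  else path
  if (!length(files)) stop("no VOC XML files under ", path)
  do.call(rbind, lapply(sort(files), read_voc_annotation))
}

#' Read / write detection JSON
#'
#' Detections are exchanged as a JSON list of
#' `{image_id, bbox: [x, y, w, h], score}` (COCO bbox dialect), converted to
#' the internal corner convention on read.
#'
#' @param dets data frame with `image_id`, box columns and `score`.
#' @param path JSON file.
#' @return `read_detections_json()` returns the detections data frame.
#' @export
write_detections_json <- function(dets, path) {
  out <- lapply(seq_len(nrow(dets)), function(k) {
    d <- dets[k, ]
    list(image_id = as.character(d$image_id),
         bbox = c(d$x_min, d$y_min, d$x_max - d$x_min, d$y_max - d$y_min),
         score = d$score)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_detections_json
#' @export
read_detections_json <- function(path) {
  obj <- jsonlite::read_json(path)
  rows <- lapply(obj, function(d) {
    bb <- unlist(d$bbox)
    data.frame(image_id = d$image_id, x_min = bb[1], y_min = bb[2],
               x_max = bb[1] + bb[3], y_max = bb[2] + bb[4], score = d$score)
  })
  if (length(rows)) do.call(rbind, rows)
  else data.frame(image_id = character(0), x_min = numeric(0),
                  y_min = numeric(0), x_max = numeric(0), y_max = numeric(0),
                  score = numeric(0))
}

#' Load an on-disk dataset
#'
#' Reads the manifest, images and COCO annotations written by
#' [generate_dataset()].
#'
#' @param dir dataset directory.
#' @param split `"train"`, `"val"` or `"all"`.
#' @return list of `list(image, boxes, image_id)` samples.
#' @export
load_dataset <- function(dir, split = c("all", "train", "val")) {
  split <- match.arg(split)
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  ann <- read_coco_annotations(file.path(dir, "annotations.json"))
  out <- list()
  for (e in man$images) {
    if (split != "all" && e$split != split) next
    img <- png::readPNG(file.path(dir, e$file))
    b <- ann[ann$image_id == e$image_id,
             c("x_min", "y_min", "x_max", "y_max"), drop = FALSE]
    out[[length(out) + 1L]] <- list(image = img, boxes = b, image_id = e$image_id)
  }
  out
}
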