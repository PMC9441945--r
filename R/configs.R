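#' Bundled model configurations
#'
#' Returns the configuration for any rung of the ablation ladder between the
#' YOLOv5s baseline and MGA-YOLO.  The ladder replaces, cumulatively:
#' ordinary convolutions and C3 stages by Ghost modules and C3Ghost stages
#' throughout the network (`"yolov5s-ghost"`); the inner blocks of the five
#' feature-fusion C3 stages (the post-SPP P5 stage and the four PANet stages)
#' by inverted residual bottlenecks, first without attention
#' (`"yolov5s-ghost-c3mb"`), then with squeeze-excitation, coordinate
#' attention or CBAM in the attention slot; an extra stride-64 P6 prediction
#' head made from a single stride-2 Ghost module after the P5 output
#' (`"yolov5s-ghost-c3mb-cbam-head"`); and finally GELU in place of SiLU for
#' every activation (`"mga-yolo"`).
#'
#' @param variant one of `"yolov5s"`, `"yolov5s-ghost"`,
#'   `"yolov5s-ghost-c3mb"`, `"yolov5s-ghost-c3mb-se"`,
#'   `"yolov5s-ghost-c3mb-ca"`, `"yolov5s-ghost-c3mb-cbam"`,
#'   `"yolov5s-ghost-c3mb-cbam-head"`, `"mga-yolo"`.
#' @param nc number of object classes (4 for the apple-leaf disease setting:
#'   healthy, rust, scab, black rot).
#' @param depth_multiple,width_multiple compound scaling factors; the "s"
#'   size uses 0.33 / 0.50.
#' @param activation override the variant's activation (`"silu"`, `"gelu"`,
#'   `"leaky_relu"`).
#' @return a configuration list accepted by [build_model()].
#' @examples
#' cfg <- mga_config("mga-yolo")
#' cfg$activation
#' @export
mga_config <- function(variant = c("mga-yolo", "yolov5s", "yolov5s-ghost",
                                   "yolov5s-ghost-c3mb", "yolov5s-ghost-c3mb-se",
                                   "yolov5s-ghost-c3mb-ca",
                                   "yolov5s-ghost-c3mb-cbam",
                                   "yolov5s-ghost-c3mb-cbam-head"),
                       nc = 4, depth_multiple = 0.33, width_multiple = 0.50,
                       activation = NULL) {
  variant <- match.arg(variant)
  ghost <- variant != "yolov5s"
  mb_attention <- switch(variant,
    "yolov5s" = , "yolov5s-ghost" = NA_character_,
    "yolov5s-ghost-c3mb" = "none",
    "yolov5s-ghost-c3mb-se" = "se",
    "yolov5s-ghost-c3mb-ca" = "ca",
    "cbam")
  c3mb <- !is.na(mb_attention)
  p6 <- variant %in% c("yolov5s-ghost-c3mb-cbam-head", "mga-yolo")
  act <- activation %||% if (variant == "mga-yolo") "gelu" else "silu"

  cv <- if (ghost) "ghost_conv" else "conv"
  c3 <- if (ghost) "c3ghost" else "c3"
  fuse <- function(c2) {
    if (c3mb) list(from = -1, repeats = 3, kind = "c3mb",
                   args = list(c2, FALSE, mb_attention, 6))
    else list(from = -1, repeats = 3, kind = c3, args = list(c2, FALSE))
  }
  backbone <- list(
    list(from = -1, repeats = 1, kind = "focus", args = list(64, 3)),
    list(from = -1, repeats = 1, kind = cv, args = list(128, 3, 2)),
    list(from = -1, repeats = 3, kind = c3, args = list(128, TRUE)),
    list(from = -1, repeats = 1, kind = cv, args = list(256, 3, 2)),
    list(from = -1, repeats = 9, kind = c3, args = list(256, TRUE)),
    list(from = -1, repeats = 1, kind = cv, args = list(512, 3, 2)),
    list(from = -1, repeats = 9, kind = c3, args = list(512, TRUE)),
    list(from = -1, repeats = 1, kind = cv, args = list(1024, 3, 2)),
    list(from = -1, repeats = 1, kind = "spp", args = list(1024, c(5, 9, 13))),
    fuse(1024))
  head <- list(
    list(from = -1, repeats = 1, kind = cv, args = list(512, 1, 1)),
    list(from = -1, repeats = 1, kind = "upsample", args = list()),
    list(from = c(-1, 7), repeats = 1, kind = "concat", args = list()),
    fuse(512),
    list(from = -1, repeats = 1, kind = cv, args = list(256, 1, 1)),
    list(from = -1, repeats = 1, kind = "upsample", args = list()),
    list(from = c(-1, 5), repeats = 1, kind = "concat", args = list()),
    fuse(256),
    list(from = -1, repeats = 1, kind = cv, args = list(256, 3, 2)),
    list(from = c(-1, 15), repeats = 1, kind = "concat", args = list()),
    fuse(512),
    list(from = -1, repeats = 1, kind = cv, args = list(512, 3, 2)),
    list(from = c(-1, 11), repeats = 1, kind = "concat", args = list()),
    fuse(1024))
  if (p6) {
    head <- c(head, list(
      list(from = -1, repeats = 1, kind = "ghost_conv", args = list(1024, 3, 2)),
      list(from = c(18, 21, 24, 25), repeats = 1, kind = "detect",
           args = list())))
    anchors <- list(c(19, 27, 44, 40, 38, 94),
                    c(96, 68, 86, 152, 180, 137),
                    c(140, 301, 303, 264, 238, 542),
                    c(436, 615, 739, 380, 925, 792))
  } else {
    head <- c(head, list(
      list(from = c(18, 21, 24), repeats = 1, kind = "detect", args = list())))
    anchors <- list(c(10, 13, 16, 30, 33, 23),
                    c(30, 61, 62, 45, 59, 119),
                    c(116, 90, 156, 198, 373, 326))
  }
  list(name = variant, nc = nc, depth_multiple = depth_multiple,
       width_multiple = width_multiple, activation = act, anchors = anchors,
       backbone = backbone, head = head)
}

#' Names of all bundled ablation-ladder variants
#' @return character vector in ladder order.
#' @export
mga_variants <- function() {
  c("yolov5s", "yolov5s-ghost", "yolov5s-ghost-c3mb", "yolov5s-ghost-c3mb-se",
    "yolov5s-ghost-c3mb-ca", "yolov5s-ghost-c3mb-cbam",
    "yolov5s-ghost-c3mb-cbam-head", "mga-yolo")
}

#' Read / write model configurations as YAML
#'
#' Configurations round-trip through a YAML dialect mirroring the in-memory
#' list: scalar fields, per-head anchor vectors and the backbone/head layer
#' lists.
#'
#' @param path file path.
#' @param cfg a configuration list.
#' @return `read_model_config()` returns the configuration list;
#'   `write_model_config()` returns `path` invisibly.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  y$anchors <- lapply(y$anchors, as.numeric)
  fix <- function(layers) lapply(layers, function(l) {
    list(from = as.integer(unlist(l$from)), repeats = as.integer(l$repeats),
         kind = l$kind, args = as.list(l$args))
  })
  y$backbone <- fix(y$backbone)
  y$head <- fix(y$head)
  y
}

#' @rdname read_model_config
#' @export
write_model_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
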