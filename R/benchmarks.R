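#' Published sugarbeet/weed detection benchmark rows
#'
#' Reference weed-class metrics reported for the sugarbeet field benchmark:
#' the module-ablation grid of a YOLOv5-based detector (transformer
#' encoder, CFFI and ASFF toggles) and a comparison across detector
#' families.  Values are fractions in `[0, 1]` as printed in the original
#' benchmark tables; they are used as worked-example inputs for the F1
#' arithmetic, not as targets the desk-scale models reproduce.
#'
#' @return A data.frame with one row per model configuration.
#' @export
ablation_benchmark <- function() {
  data.frame(
    model = c("baseline",
              "baseline+transformer",
              "baseline+cffi",
              "baseline+transformer+cffi",
              "baseline+transformer+cffi+asff"),
    use_transformer = c(FALSE, TRUE, FALSE, TRUE, TRUE),
    use_cffi = c(FALSE, FALSE, TRUE, TRUE, TRUE),
    use_asff = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    recall_weed = c(0.757, 0.870, 0.840, 0.860, 0.900),
    precision_weed = c(0.474, 0.481, 0.480, 0.492, 0.573),
    f1_weed = c(0.582, 0.619, 0.610, 0.625, 0.700),
    ap_weed = c(0.695, 0.778, 0.779, 0.798, 0.808),
    map50 = c(0.841, 0.885, 0.885, 0.894, 0.900),
    map50_95 = c(0.520, 0.579, 0.581, 0.586, 0.580),
    stringsAsFactors = FALSE)
}

#' @rdname ablation_benchmark
#' @export
detector_benchmark <- function() {
  data.frame(
    model = c("faster_rcnn", "ssd", "se_yolov3", "yolov4", "yolov7",
              "improved_yolov5"),
    recall_weed = c(0.810, 0.740, 0.800, 0.835, 0.780, 0.900),
    precision_weed = c(0.486, 0.451, 0.481, 0.472, 0.493, 0.573),
    f1_weed = c(0.607, 0.560, 0.600, 0.603, 0.604, 0.700),
    map50 = c(0.866, 0.814, 0.836, 0.863, 0.872, 0.900),
    stringsAsFactors = FALSE)
}
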