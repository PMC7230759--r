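# Threshold-ladder lookup shared by the four point-scoring models.
# A component awards points[k] where k is the number of thresholds the
# intake exceeds (strictly, or >= for "ge" ladders such as the
# Nutri-Score added-fats saturated-fat ratio). Ladders are validated
# monotone at config load.

component_points <- function(value, comp) {
  thr <- as.numeric(comp$thresholds)
  pts <- if (is.null(comp$points)) seq_along(thr) else as.numeric(comp$points)
  hit <- if (identical(comp$comparator, "ge")) value >= thr else value > thr
  k <- sum(hit)
  if (k == 0) 0 else pts[[k]]
}

# map a final score to a label via ascending upper bounds
grade_from_bounds <- function(score, labels, upper) {
  idx <- which(score <= as.numeric(upper))
  if (length(idx) == 0) {
    stop_config("score exceeds every class boundary; boundary table malformed")
  }
  labels[[min(idx)]]
}

new_score_breakdown <- function(model, version, category, points,
                                negative_total, positive_total,
                                protein_suppressed, final_score,
                                grade, healthier) {
  structure(
    list(model = model, version = version, category = category,
         points = points, negative_total = negative_total,
         positive_total = positive_total,
         protein_suppressed = protein_suppressed,
         final_score = final_score, grade = grade, healthier = healthier),
    class = "fop_score")
}

#' @export
print.fop_score <- function(x, ...) {
  cat(sprintf("<%s %s> category=%s N=%s P=%s score=%s grade=%s healthier=%s\n",
              x$model, x$version, x$category, x$negative_total,
              x$positive_total, x$final_score, x$grade, x$healthier))
  invisible(x)
}
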