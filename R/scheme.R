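#' Define a tissue label scheme
#'
#' A label scheme names the tissue classes used for segmentation, marks which
#' of them are tumor-related (these are merged into the gross tumor volume,
#' GTV), and identifies the non-lesion background class that removed
#' components and unlabeled tissue fall back to.
#'
#' @param classes character vector of class names; ids are assigned
#'   contiguously from 0 in the given order.
#' @param tumor_classes names (or ids) of the classes merged into the GTV.
#' @param background name (or id) of the non-lesion class.
#' @return an object of class `label_scheme` with a `classes` tibble
#'   (`class_id`, `name`), `tumor_class_ids` and `background_id`.
#' @export
#' @examples
#' label_scheme(c("Normal", "Necrosis", "Edema", "NonEnhancing", "Enhancing"),
#'              tumor_classes = c("Necrosis", "NonEnhancing", "Enhancing"),
#'              background = "Normal")
label_scheme <- function(classes, tumor_classes, background) {
  stopifnot(is.character(classes), length(classes) >= 2L, !anyDuplicated(classes))
  ids <- seq_along(classes) - 1L
  names(ids) <- classes
  resolve <- function(x) {
    if (is.character(x)) {
      miss <- setdiff(x, classes)
      if (length(miss)) stop("unknown class name(s): ", paste(miss, collapse = ", "))
      unname(ids[x])
    } else as.integer(x)
  }
  tumor_ids <- resolve(tumor_classes)
  bg <- resolve(background)
  stopifnot(length(bg) == 1L, bg %in% ids, all(tumor_ids %in% ids))
  if (length(tumor_ids) == 0L || bg %in% tumor_ids)
    stop("tumor classes must be nonempty and exclude the background class")
  structure(
    list(
      classes = tibble::tibble(class_id = ids, name = classes),
      tumor_class_ids = sort(tumor_ids),
      background_id = bg
    ),
    class = "label_scheme"
  )
}

#' @export
print.label_scheme <- function(x, ...) {
  cat("<label_scheme> ", nrow(x$classes), " classes; GTV = {",
      paste(class_names(x)[x$classes$class_id %in% x$tumor_class_ids],
            collapse = ", "),
      "}; background = ", class_names(x)[x$classes$class_id == x$background_id],
      "\n", sep = "")
  invisible(x)
}

class_ids <- function(scheme) scheme$classes$class_id
class_names <- function(scheme) scheme$classes$name
n_classes <- function(scheme) nrow(scheme$classes)

#' Built-in label schemes
#'
#' `scheme_gb6()` is the six-category scheme used for interactive longitudinal
#' glioblastoma volumetry (Contrast-Enhancing Tumor, Non-Enhancing Tumor,
#' Edema, Cerebrospinal Fluid, Rest, Air); `Rest` (normal intracranial tissue)
#' is the background and the GTV merges the enhancing and non-enhancing tumor
#' classes.  `scheme_brats5()` is the five-class scheme of multi-rater glioma
#' challenge data (Normal, Necrosis, Edema, Non-Enhancing, Contrast-Enhancing);
#' GTV merges necrosis with the two tumor classes.
#'
#' @return a [label_scheme()].
#' @export
scheme_gb6 <- function() {
  label_scheme(
    c("Air", "Rest", "CSF", "Edema", "NonEnhancing", "Enhancing"),
    tumor_classes = c("NonEnhancing", "Enhancing"),
    background = "Rest"
  )
}

#' @rdname scheme_gb6
#' @export
scheme_brats5 <- function() {
  label_scheme(
    c("Normal", "Necrosis", "Edema", "NonEnhancing", "Enhancing"),
    tumor_classes = c("Necrosis", "NonEnhancing", "Enhancing"),
    background = "Normal"
  )
}
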