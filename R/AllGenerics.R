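#' Accessors for gelimetry classes
#'
#' Small accessor generics so user code never reaches into slots: normalized
#' positions and brightness values of a profile, the PWM duty level, the
#' fitted-polynomial error, the per-level scaling constants and their
#' baseline, and the linearity score.
#'
#' @param x a gelimetry object.
#' @return the corresponding slot value; see the class documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("pwmLevel", function(x) standardGeneric("pwmLevel"))

#' @rdname accessors
#' @export
setGeneric("fitOrder", function(x) standardGeneric("fitOrder"))

#' @rdname accessors
#' @export
setGeneric("fitError", function(x) standardGeneric("fitError"))

#' @rdname accessors
#' @export
setGeneric("scalingConstants", function(x) standardGeneric("scalingConstants"))

#' @rdname accessors
#' @export
setGeneric("baselineConstants", function(x) standardGeneric("baselineConstants"))

#' @rdname accessors
#' @export
setGeneric("scalingErrors", function(x) standardGeneric("scalingErrors"))

#' @rdname accessors
#' @export
setGeneric("linearityRMSE", function(x) standardGeneric("linearityRMSE"))

#' @rdname accessors
#' @export
setGeneric("pwmLevels", function(x) standardGeneric("pwmLevels"))

#' @rdname accessors
#' @export
setGeneric("referenceLevel", function(x) standardGeneric("referenceLevel"))

#' @rdname accessors
#' @export
setGeneric("bandVolumes", function(x) standardGeneric("bandVolumes"))

#' @rdname accessors
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))

#' @rdname accessors
#' @export
setGeneric("snr", function(x) standardGeneric("snr"))
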