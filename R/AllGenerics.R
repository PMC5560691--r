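#' @import methods
#' @importFrom stats dnorm pnorm qnorm optim p.adjust t.test wilcox.test
#'   quantile rnorm runif sd complete.cases setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

#' @export
setGeneric("cqValues", function(object, ...) standardGeneric("cqValues"))

#' @export
setGeneric("isCensored", function(object, ...) standardGeneric("isCensored"))

#' @export
setGeneric("lodValue", function(object, ...) standardGeneric("lodValue"))

#' @export
setGeneric("groupLabels", function(object, ...) standardGeneric("groupLabels"))

#' @export
setGeneric("isReference", function(object, ...) standardGeneric("isReference"))

#' @export
setGeneric("censoredFraction",
           function(object, by = c("overall", "target", "sample", "group"))
             standardGeneric("censoredFraction"))

#' @export
setGeneric("fitUCNR", function(object, ...) standardGeneric("fitUCNR"))
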