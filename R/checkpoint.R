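# Model checkpointing: one archive holding the architecture configuration,
# every parameter tensor of the five sub-networks (the shared encoder is
# stored once) and the batch-norm running statistics.

walk_modules <- function(mod, fn) {
  seen <- new.env(parent = emptyenv())
  rec <- function(m, prefix) {
    key <- as.character(m$mid)
    if (!is.null(seen[[key]])) return(invisible(NULL))
    seen[[key]] <- TRUE
    fn(m, prefix)
    for (nm in names(m$children)) rec(m$children[[nm]], paste0(prefix, nm, "."))
  }
  rec(mod, "")
  invisible(NULL)
}

#' Save a model checkpoint
#'
#' @param model a [cirf_model()]
#' @param path output file (RDS archive)
#' @return `path`, invisibly
#' @export
save_model <- function(model, path) {
  params <- list(); buffers <- list()
  walk_modules(model, function(m, prefix) {
    for (nm in names(m$params)) params[[paste0(prefix, nm)]] <<- m$params[[nm]]$value
    if (!is.null(m$running_mean)) {
      buffers[[paste0(prefix, "running_mean")]] <<- m$running_mean
      buffers[[paste0(prefix, "running_var")]] <<- m$running_var
    }
  })
  saveRDS(list(cfg = model$cfg, params = params, buffers = buffers, format = 1L), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [save_model()]
#' @return a [cirf_model()] with restored weights
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  ck <- readRDS(path)
  model <- cirf_model(ck$cfg, seed = 0L)
  walk_modules(model, function(m, prefix) {
    for (nm in names(m$params)) {
      key <- paste0(prefix, nm)
      if (is.null(ck$params[[key]])) stop("checkpoint missing parameter ", key)
      stored <- ck$params[[key]]
      cur <- m$params[[nm]]$value
      if (!identical(dim(stored) %||% length(stored), dim(cur) %||% length(cur)))
        stop("checkpoint shape mismatch for ", key)
      m$params[[nm]]$value <- stored
    }
    if (!is.null(m$running_mean)) {
      m$running_mean <- ck$buffers[[paste0(prefix, "running_mean")]]
      m$running_var <- ck$buffers[[paste0(prefix, "running_var")]]
    }
  })
  model
}
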