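# Shared fixture builders (all data generated in code).

# a junction_profile built directly from a function of position
make_profile <- function(fun, length_um = 20, pixel_size_um = 0.2) {
  n_half <- ceiling(length_um / pixel_size_um / 2)
  pos <- seq(-n_half, n_half) * pixel_size_um
  structure(data.frame(pos_um = pos, intensity = fun(pos)),
            pixel_size_um = pixel_size_um, width_px = 1,
            class = c("junction_profile", "data.frame"))
}

# model without interactions: pure basal/removal kinetics
uncoupled_model <- function(nodes = c("A", "B"), basal = 0, removal = 1) {
  srgap_network(nodes,
                edges = data.frame(source = character(0),
                                   target = character(0),
                                   sign = character(0),
                                   strength = numeric(0), K = numeric(0),
                                   hill = numeric(0)),
                basal = stats::setNames(rep(basal, length(nodes)), nodes),
                removal = stats::setNames(rep(removal, length(nodes)), nodes))
}

# rate law rebuilt directly from a model's declared fields; serves as an
# oracle independent of the package's integration internals
oracle_rhs <- function(model) {
  function(x) {
    dx <- model$basal - x * model$removal
    for (i in seq_len(nrow(model$edges))) {
      e <- model$edges[i, ]
      h <- e$strength * max(x[e$source], 0)^e$hill /
        (e$K^e$hill + max(x[e$source], 0)^e$hill)
      if (e$sign == "stimulation") dx[e$target] <- dx[e$target] + h
      else dx[e$target] <- dx[e$target] - x[e$target] * h
    }
    if (!is.null(model$exogenous)) dx[model$exogenous] <- 0
    dx
  }
}

# full synth -> fit -> report pipeline through the CLI dispatcher
run_pipeline <- function(root, seed = 11) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  sub <- function(...) file.path(root, ...)
  jmech_cli(c("synth", "recoil", "--out", sub("recoil"), "--seed", seed))
  jmech_cli(c("fit-recoil", "--in", sub("recoil", "recoil.csv"),
              "--control", "control", "--out", sub("recoil_fits.csv")))
  jmech_cli(c("synth", "frap", "--out", sub("frap"), "--seed", seed))
  jmech_cli(c("fit-frap", "--in", sub("frap", "frap.csv"),
              "--out", sub("frap_fits.csv")))
  jmech_cli(c("synth", "image", "--out", sub("img"), "--seed", seed))
  jmech_cli(c("quantify", "--image", sub("img", "image.tif"),
              "--roi", sub("img", "roi.csv"), "--measure", "peak",
              "--pixel-size", "0.2", "--out", sub("quantify.csv")))
  jmech_cli(c("synth", "tracks", "--out", sub("tracks"), "--seed", seed))
  jmech_cli(c("msd", "--in", sub("tracks", "tracks.csv"),
              "--horizon", "360", "--control", "control",
              "--out", sub("msd.csv")))
  fits <- utils::read.csv(sub("frap_fits.csv"))
  fits$value <- fits$Mf
  utils::write.csv(fits, sub("frap_values.csv"), row.names = FALSE)
  jmech_cli(c("report", "--in", sub("frap_values.csv"), "--value", "value",
              "--control", "control", "--out", sub("report.csv")))
  invisible(root)
}

# independent finite-difference Jacobian used as a stability oracle
oracle_jacobian <- function(rhs, x, h = 1e-6) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (rhs(xp) - rhs(xm)) / (2 * h)
  }
  J
}
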