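setMethod("show", "MP2RAGEProtocol", function(object) {
  cat("MP2RAGE protocol\n")
  cat(sprintf("  TI1/TI2/TR: %g/%g/%g ms;  alpha1/alpha2: %g/%g deg\n",
              object@TI1, object@TI2, object@TR, object@alpha1, object@alpha2))
  cat(sprintf("  readout: %g pulses x %g ms;  inversion efficiency: %g\n",
              object@nReadout, object@readoutTR, object@inversionEfficiency))
})

setMethod("show", "SignalDictionary", function(object) {
  cat("MP2RAGE signal dictionary\n")
  cat(sprintf("  R1 grid: [%g, %g] 1/s, %d points\n",
              min(object@r1Grid), max(object@r1Grid), length(object@r1Grid)))
  cat(sprintf("  B1 grid: [%g, %g], %d points\n",
              min(object@b1Grid), max(object@b1Grid), length(object@b1Grid)))
})

setMethod("show", "GLMFit", function(object) {
  cat("Covariate GLM fit (dof =", object@dof, ")\n")
  print(round(rbind(beta = object@beta, se = object@se,
                    t = object@t, z = object@z), 4))
})

setMethod("show", "NormativeModel", function(object) {
  lbl <- paste(object@roi, object@metric, object@statistic, sep = " / ")
  cat("Gaussian-process normative model:", lbl, "\n")
  cat(sprintf("  n = %d training observations, age range [%.1f, %.1f] years\n",
              length(object@xTrain),
              object@xMean + min(object@xTrain) * object@xSd,
              object@xMean + max(object@xTrain) * object@xSd))
  cat("  hyperparameters (standardised scale):\n")
  print(round(object@hyper, 5))
  cat(sprintf("  log marginal likelihood: %.3f\n", object@logML))
})

setMethod("show", "SpatialGradientFit", function(object) {
  cat("Spatial gradient fit (", object@hemisphere, " hemisphere convention)\n",
      sep = "")
  cat(sprintf("  p0 = %.5g;  gradient LM/PA/IS = %.4g / %.4g / %.4g per mm\n",
              object@p0, object@gradient[["LM"]], object@gradient[["PA"]],
              object@gradient[["IS"]]))
  cat(sprintf("  centre (%.2f, %.2f, %.2f) mm;  %d voxels;  rmse %.4g\n",
              object@centre[1], object@centre[2], object@centre[3],
              object@nVoxels, object@rmse))
})
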