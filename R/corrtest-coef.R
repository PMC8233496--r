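# Frozen logistic-regression coefficients of the CorrTest classifier:
# intercept, pc_pearson, pc_spearman, sib_pearson, sib_spearman.
# Trained on the package's own simulator by scripts/train_corrtest.R
# (independent-lognormal vs autocorrelated branch rates; seed and grid
# recorded there). Regenerate by running that script and pasting its
# output here.
.CORRTEST_COEF <- c(
  intercept = 343.819157, pc_pearson = -521.434202, pc_spearman = 23.784177,
  sib_pearson = 175.671248, sib_spearman = 4.216650
)
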