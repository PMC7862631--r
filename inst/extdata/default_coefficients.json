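{
  "HS": {
    "rates": {
      "survival": {
        "family": "binomial",
        "link": "logit",
        "size_scale": "log",
        "sigma_plot": 0.3,
        "terms": {
          "(Intercept)": {
            "estimate": -12.5741838773667,
            "se": null
          },
          "size": {
            "estimate": 0.8,
            "se": null
          },
          "size2": {
            "estimate": -0.05,
            "se": null
          },
          "block_b": {
            "estimate": 1.116,
            "se": 0.268
          },
          "intra": {
            "estimate": -0.481,
            "se": 0.359
          },
          "inter": {
            "estimate": -0.627,
            "se": 0.069
          },
          "winter_min_temp": {
            "estimate": 0.014,
            "se": 0.001
          },
          "spring_rain": {
            "estimate": 0.073,
            "se": 0.004
          },
          "summer_wb": {
            "estimate": -0.091,
            "se": 0.091
          }
        }
      },
      "growth": {
        "family": "gaussian",
        "link": "identity",
        "size_scale": "log",
        "sigma_plot": 0.3,
        "terms": {
          "(Intercept)": {
            "estimate": 1.68241691664033,
            "se": null
          },
          "size": {
            "estimate": 6,
            "se": null
          },
          "block_b": {
            "estimate": -0.722,
            "se": 0.145
          },
          "intra": {
            "estimate": 0.454,
            "se": 0.17
          },
          "inter": {
            "estimate": 0.075,
            "se": 0.038
          },
          "winter_min_temp": {
            "estimate": -0.005,
            "se": 0.001
          },
          "spring_rain": {
            "estimate": -0.028,
            "se": 0.002
          },
          "summer_wb": {
            "estimate": -0.021,
            "se": 0.059
          }
        },
        "sigma_resid": 5
      },
      "reproduction": {
        "family": "binomial",
        "link": "logit",
        "size_scale": "log",
        "sigma_plot": 0.3,
        "terms": {
          "(Intercept)": {
            "estimate": -79.9869811764577,
            "se": null
          },
          "size": {
            "estimate": 0.6,
            "se": null
          },
          "block_b": {
            "estimate": -1.471,
            "se": 0.408
          },
          "intra": {
            "estimate": 0.872,
            "se": 0.5
          },
          "inter": {
            "estimate": 2.51,
            "se": 0.114
          },
          "winter_min_temp": {
            "estimate": -0.042,
            "se": 0.002
          },
          "spring_rain": {
            "estimate": 0.507,
            "se": 0.147
          }
        }
      },
      "fecundity": {
        "family": "poisson",
        "link": "log",
        "size_scale": "log",
        "sigma_plot": 0.3,
        "terms": {
          "(Intercept)": {
            "estimate": -8.80547018598809,
            "se": null
          },
          "size": {
            "estimate": 1,
            "se": null
          },
          "block_b": {
            "estimate": -4.731,
            "se": 0.181
          },
          "intra": {
            "estimate": 0.154,
            "se": 0.102
          },
          "inter": {
            "estimate": -1.093,
            "se": 0.022
          },
          "winter_min_temp": {
            "estimate": 0.016,
            "se": 0
          },
          "spring_rain": {
            "estimate": 0.054,
            "se": 0.002
          },
          "summer_wb": {
            "estimate": 0.365,
            "se": 0.162
          }
        }
      }
    },
    "recruit": {
      "meanlog": 0.693147180559945,
      "sdlog": 0.5
    }
  },
  "LS": {
    "rates": {
      "survival": {
        "family": "binomial",
        "link": "logit",
        "size_scale": "log",
        "sigma_plot": 0.3,
        "terms": {
          "(Intercept)": {
            "estimate": -12.3499603554186,
            "se": null
          },
          "size": {
            "estimate": 0.8,
            "se": null
          },
          "size2": {
            "estimate": -0.05,
            "se": null
          },
          "block_b": {
            "estimate": 0.454,
            "se": 0.893
          },
          "intra": {
            "estimate": -2.03,
            "se": 0.611
          },
          "inter": {
            "estimate": -0.69,
            "se": 0.2
          },
          "winter_min_temp": {
            "estimate": 0.005,
            "se": 0.003
          },
          "spring_rain": {
            "estimate": 0.084,
            "se": 0.009
          }
        }
      },
      "growth": {
        "family": "gaussian",
        "link": "identity",
        "size_scale": "log",
        "sigma_plot": 0.3,
        "terms": {
          "(Intercept)": {
            "estimate": 8.88141691664033,
            "se": null
          },
          "size": {
            "estimate": 6,
            "se": null
          },
          "intra": {
            "estimate": -0.363,
            "se": 0.312
          },
          "inter": {
            "estimate": 0.622,
            "se": 0.076
          },
          "winter_min_temp": {
            "estimate": -0.009,
            "se": 0.001
          },
          "spring_rain": {
            "estimate": -0.074,
            "se": 0.005
          }
        },
        "sigma_resid": 5
      },
      "reproduction": {
        "family": "binomial",
        "link": "logit",
        "size_scale": "log",
        "sigma_plot": 0.3,
        "terms": {
          "(Intercept)": {
            "estimate": -43.5063811764578,
            "se": null
          },
          "size": {
            "estimate": 0.6,
            "se": null
          },
          "block_b": {
            "estimate": 4.511,
            "se": 1.922
          },
          "spring_rain": {
            "estimate": 0.27,
            "se": 0.412
          }
        }
      },
      "fecundity": {
        "family": "poisson",
        "link": "log",
        "size_scale": "log",
        "sigma_plot": 0.3,
        "terms": {
          "(Intercept)": {
            "estimate": -29.6753137373023,
            "se": null
          },
          "size": {
            "estimate": 1,
            "se": null
          },
          "block_b": {
            "estimate": -1.432,
            "se": 0.458
          },
          "intra": {
            "estimate": -1.298,
            "se": 0.424
          },
          "inter": {
            "estimate": -0.532,
            "se": 0.072
          },
          "winter_min_temp": {
            "estimate": -0.002,
            "se": 0.001
          },
          "spring_rain": {
            "estimate": 0.158,
            "se": 0.007
          },
          "summer_wb": {
            "estimate": -0.17,
            "se": 0.304
          }
        }
      }
    },
    "recruit": {
      "meanlog": 0.693147180559945,
      "sdlog": 0.5
    }
  }
}
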