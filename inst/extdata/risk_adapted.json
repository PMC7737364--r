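{
  "strategy": "risk_adapted",
  "root": {
    "type": "chance",
    "branches": [
      {
        "p": {
          "param": "pLowRisk"
        },
        "child": {
          "type": "chance",
          "branches": [
            {
              "p": {
                "param": "pRelapseLowrisk"
              },
              "child": {
                "type": "chance",
                "branches": [
                  {
                    "p": {
                      "param": "pRelapsePostSalvChemo"
                    },
                    "child": {
                      "type": "terminal",
                      "payoff": {
                        "sum": [
                          {
                            "param": "nSalvageCycles"
                          },
                          {
                            "product": [
                              {
                                "param": "nSecondLineCycles"
                              },
                              {
                                "param": "tSecondChemo"
                              }
                            ]
                          }
                        ]
                      }
                    }
                  },
                  {
                    "p": {
                      "complement": {
                        "param": "pRelapsePostSalvChemo"
                      }
                    },
                    "child": {
                      "type": "terminal",
                      "payoff": {
                        "param": "nSalvageCycles"
                      }
                    }
                  }
                ]
              }
            },
            {
              "p": {
                "complement": {
                  "param": "pRelapseLowrisk"
                }
              },
              "child": {
                "type": "terminal",
                "payoff": 0
              }
            }
          ]
        }
      },
      {
        "p": {
          "complement": {
            "param": "pLowRisk"
          }
        },
        "child": {
          "type": "chance",
          "branches": [
            {
              "p": {
                "param": "pRelapsePostPrimChemo"
              },
              "child": {
                "type": "chance",
                "branches": [
                  {
                    "p": {
                      "param": "pRelapsePostSalvChemo"
                    },
                    "child": {
                      "type": "terminal",
                      "payoff": {
                        "sum": [
                          {
                            "param": "nPrimaryCycles"
                          },
                          {
                            "param": "nSalvageCycles"
                          },
                          {
                            "product": [
                              {
                                "param": "nSecondLineCycles"
                              },
                              {
                                "param": "tSecondChemo"
                              }
                            ]
                          }
                        ]
                      }
                    }
                  },
                  {
                    "p": {
                      "complement": {
                        "param": "pRelapsePostSalvChemo"
                      }
                    },
                    "child": {
                      "type": "terminal",
                      "payoff": {
                        "sum": [
                          {
                            "param": "nPrimaryCycles"
                          },
                          {
                            "param": "nSalvageCycles"
                          }
                        ]
                      }
                    }
                  }
                ]
              }
            },
            {
              "p": {
                "complement": {
                  "param": "pRelapsePostPrimChemo"
                }
              },
              "child": {
                "type": "terminal",
                "payoff": {
                  "param": "nPrimaryCycles"
                }
              }
            }
          ]
        }
      }
    ]
  }
}
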